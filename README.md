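# qsarforge

Small-n QSAR model building in R: ordinary-least-squares regression of
potency (pIC50) on molecular descriptors, with the validation machinery the
field expects — leave-one-out cross-validation, all-subsets and
genetic-algorithm descriptor selection, and classical confidence/prediction
bands — plus the potency-unit and selectivity arithmetic used in
kinase-inhibitor structure–activity work.

## Who this is for

Medicinal and computational chemists who have a rectangular descriptor
table (one row per compound, columns of software-computed molecular
descriptors, one or more pIC50 responses with gaps) and want reproducible
multiple-linear-regression QSAR models with honest small-sample
diagnostics, rather than a black-box learner.

## The model

For n compounds and a descriptor subset of size p, the package fits

    pIC50_i = b0 + b1 x_i1 + ... + bp x_ip + e_i

by QR least squares on the raw descriptor scales and reports

- R² = 1 − RSS/TSS,
- standard error of estimate s = √(RSS/(n−p−1)),
- F = (R²/p) / ((1−R²)/(n−p−1)),
- Q²_LOO = 1 − PRESS/TSS, where PRESS accumulates the squared
  leave-one-out prediction errors eᵢ/(1−hᵢᵢ) (hat-matrix shortcut, equal to
  the explicit refit loop to machine precision).

Descriptor subsets are chosen either by exhaustive enumeration (all subsets
up to a size cap) or by a seeded genetic algorithm over binary masks
(tournament selection, uniform crossover, per-individual mutation,
elitism), with Q²_LOO as the default fitness.

The package ships a worked dataset: a series of imidazothiazole inhibitors
of the melanoma-driving V600E mutant of B-RAF kinase and of RAF1, with six
molecular descriptors (INTEGY moments IW1/IW2, flexibility FLEX, polar
surface area PSA, the acceptor–donor–donor pharmacophore count ACDODO, and
the hydrophobic-volume difference DD8) for 22 compounds, kinase-panel and
cell-line potency data included.

## Worked example

```r
library(qsarforge)

tbl <- raf_descriptor_table()
fit <- fit_mlr(tbl, "pIC50_RAF1", c("IW1", "FLEX"))
fit
#> <qsar_mlr> pIC50_RAF1 = -35.164 x IW1 + -1.360 x FLEX + 13.459
#>   n = 9, R2 = 0.970, s = 0.118, F = 95.67, Q2(LOO) = 0.941
```

Nine compounds have RAF1 potencies; their pIC50 falls by ~35 units per unit
of IW1 (hydrophilic regions concentrated off-centre hurt binding) and by
~1.4 per unit of molecular flexibility. R² near 0.97 with leave-one-out Q²
near 0.94 says the two-descriptor model predicts held-out compounds almost
as well as it fits, the signature of a stable small-n model.

The all-subsets search over the six descriptors ranks that same pair first
by cross-validated fitness:

```r
ds <- build_qsar_dataset(tbl, "pIC50_RAF1")
head(exhaustive_search(ds, max_size = 2), 2)
#> # A tibble: 2 × 7
#>   subset   descriptors  size fitness r.squared q.squared sigma
#>   <chr>    <list>      <int>   <dbl>     <dbl>     <dbl> <dbl>
#> 1 IW1+FLEX <chr [2]>       2   0.941     0.970     0.941 0.118
#> 2 IW2+FLEX <chr [2]>       2   0.747     0.901     0.747 0.213
```

Selectivity arithmetic for the lead compound:

```r
selectivity_report("1zb", raf_kinase_potency(), cells = raf_cell_viability())
#> <qsar_selectivity> 1zb vs V600E-B-RAF (IC50 0.978 nM)
#>   RAF1: 8.38-fold
#>   FLT3: 856.85-fold
#>   A375: selectivity index 20.13
#>   MDA-MB-435: selectivity index 15.69
#>   SK-MEL-28: selectivity index 24.37
#>   UACC-62: selectivity index 51.44
```

`run_reference_analysis(out_dir)` runs the whole bundled analysis —
checksum-verified fixtures, transcription cross-checks, both model refits
with leave-one-out validation, scatter data with 95% confidence/prediction
limits, the selectivity report and the kinase-panel hit list — and writes a
deterministic report bundle.

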