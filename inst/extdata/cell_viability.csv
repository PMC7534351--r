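cell_line,tissue,compound,ic50_uM,ic50_sem_uM
A375,melanoma,1zb,0.46,0.03
A375,melanoma,sorafenib,5.45,0.53
MDA-MB-435,melanoma,1zb,0.59,0.06
MDA-MB-435,melanoma,sorafenib,3.16,0.20
SK-MEL-28,melanoma,1zb,0.38,0.05
SK-MEL-28,melanoma,sorafenib,2.67,0.15
UACC-62,melanoma,1zb,0.18,0.02
UACC-62,melanoma,sorafenib,1.95,0.08
CCD1106K,normal skin,1zb,9.26,0.38
CCD1106K,normal skin,sorafenib,11.57,0.46
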