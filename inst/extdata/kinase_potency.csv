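compound,kinase,pct_inhibition,pct_sem,ic50_nM
1a,RAF1,54.04,5.07,ND
1a,V600E-B-RAF,67.62,3.61,ND
1b,RAF1,63.81,2.51,ND
1b,V600E-B-RAF,73.06,1.72,245
1c,RAF1,59.53,2.25,ND
1c,V600E-B-RAF,52.03,3.61,ND
1d,RAF1,63.44,1.62,ND
1d,V600E-B-RAF,69.37,0.05,ND
1e,RAF1,62.63,0.34,ND
1e,V600E-B-RAF,90.43,0.72,144
1f,RAF1,71.39,1.32,ND
1f,V600E-B-RAF,90.99,0.56,83.8
1g,RAF1,13.99,2.28,ND
1g,V600E-B-RAF,38.64,0.21,ND
1h,RAF1,38.67,5.01,ND
1h,V600E-B-RAF,77.90,0.11,191
1i,RAF1,55.46,1.61,ND
1i,V600E-B-RAF,85.45,0.42,142
1j,RAF1,69.84,0.52,ND
1j,V600E-B-RAF,91.40,0.48,78.2
1k,RAF1,66.14,2.60,ND
1k,V600E-B-RAF,-5.63,3.11,ND
1l,RAF1,13.09,0.12,ND
1l,V600E-B-RAF,40.59,1.72,ND
1m,RAF1,75.89,1.43,ND
1m,V600E-B-RAF,80.25,0.61,82.6
1n,RAF1,75.69,0.67,ND
1n,V600E-B-RAF,84.82,0.42,120
1o,RAF1,32.50,1.91,ND
1o,V600E-B-RAF,52.76,3.66,ND
1p,RAF1,60.68,0.95,ND
1p,V600E-B-RAF,69.65,0.40,ND
1q,RAF1,19.33,2.37,ND
1q,V600E-B-RAF,23.59,1.99,ND
1r,RAF1,97.45,0.10,45.6
1r,V600E-B-RAF,97.66,0.16,11.2
1s,RAF1,97.28,0.08,49.7
1s,V600E-B-RAF,99.54,0.23,18.4
1t,RAF1,67.56,4.79,ND
1t,V600E-B-RAF,87.74,0.38,194
1u,RAF1,74.00,0.64,ND
1u,V600E-B-RAF,95.03,0.66,45.1
1v,RAF1,59.25,2.53,ND
1v,V600E-B-RAF,90.82,0.25,100
1w,RAF1,56.61,2.15,ND
1w,V600E-B-RAF,83.65,0.47,121
1x,RAF1,32.14,0.08,ND
1x,V600E-B-RAF,56.21,0.10,ND
1y,RAF1,57.47,0.47,ND
1y,V600E-B-RAF,63.23,0.93,ND
1z,RAF1,32.12,2.26,ND
1z,V600E-B-RAF,79.41,0.56,241
1za,RAF1,51.51,3.74,ND
1za,V600E-B-RAF,71.56,3.43,ND
1zb,RAF1,99.39,0.20,8.2
1zb,V600E-B-RAF,99.48,0.09,0.978
1zb,FLT3,73.14,2.0,838
1zc,RAF1,99.32,0.23,10.5
1zc,V600E-B-RAF,101.07,1.53,1.9
1zd,RAF1,98.71,0.23,16.7
1zd,V600E-B-RAF,100.24,0.17,3.4
1ze,RAF1,86.02,1.08,468.0
1ze,V600E-B-RAF,97.81,1.67,28.8
1zf,RAF1,92.71,0.99,151.0
1zf,V600E-B-RAF,97.19,0.32,22.2
1zg,RAF1,90.78,0.22,158.0
1zg,V600E-B-RAF,98.97,0.43,15.8
1zh,RAF1,96.60,0.18,62.2
1zh,V600E-B-RAF,100.66,2.35,7.4
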