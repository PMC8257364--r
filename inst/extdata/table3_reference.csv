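system,auc_pct,cutoff,acc_pct,sen_pct,spc_pct,cui_plus,cui_minus
Optimal CPN system,95.11,-,86.84,90.00,84.78,0.7147,0.7873
FAQ cut-off,88.80,0/1,86.84,83.33,89.13,0.6944,0.7944
MMSE cut-off,80.65,28/29,73.68,80.00,69.57,0.5053,0.5858
GDS cut-off,56.12,2/3,64.47,23.33,91.30,0.1485,0.5900
Neurologist,-,-,77.63,86.67,71.74,0.5778,0.6398
Geriatrician,-,-,78.95,56.67,93.48,0.4817,0.7178
PCP1,-,-,69.74,23.33,100.00,0.2333,0.6667
PCP2,-,-,68.42,20.00,100.00,0.2000,0.6571
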