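subset,auc_pct,acc_pct,sen_pct,spc_pct
Age + MMSE + FAQ,95.11,86.84,90.00,84.78
MMSE + FAQ,94.42,85.53,90.00,82.61
Age + MMSE + FAQ + GDS,92.97,88.16,86.67,89.13
Age + FAQ,92.25,82.90,96.67,73.91
MMSE + FAQ + GDS,90.98,81.58,86.67,78.26
MMSE + FAQ + GDS + YOE,90.87,86.84,80.00,91.30
Age + MMSE + FAQ + YOE,90.22,86.84,70.00,97.83
FAQ + GDS,90.22,84.21,73.33,91.30
Age + FAQ + GDS,88.44,81.58,86.67,78.26
Age + MMSE + FAQ + GDS + YOE,87.97,88.16,80.00,93.48
MMSE + FAQ + YOE,87.75,82.90,70.00,91.30
FAQ + YOE,86.70,85.53,80.00,89.13
MMSE + GDS + YOE,86.49,80.26,73.33,84.78
Age + MMSE + GDS,86.23,84.21,80.00,86.96
Age + MMSE,86.23,80.26,70.00,86.96
Age + MMSE + YOE,86.09,80.26,70.00,86.96
Age + MMSE + GDS + YOE,85.58,78.95,76.67,80.44
MMSE + GDS,85.36,73.68,93.33,60.87
MMSE + YOE,84.31,75.00,93.33,63.04
Age + FAQ + YOE,82.17,81.58,70.00,89.13
FAQ + GDS + YOE,80.58,73.68,83.33,67.39
Age + FAQ + GDS + YOE,80.00,80.26,60.00,93.48
Age + GDS,71.92,65.79,76.67,58.70
Age + GDS + YOE,66.88,60.53,83.33,45.65
Age + YOE,65.69,65.79,56.67,71.74
GDS + YOE,63.41,53.95,90.00,30.44
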