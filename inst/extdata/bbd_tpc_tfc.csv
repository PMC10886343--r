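run,ec_pct,time_min,temp_c,coded_x1,coded_x2,coded_x3,tpc_exp,tpc_sd,tpc_rsm_pred,tpc_ann_pred,tfc_exp,tfc_sd,tfc_rsm_pred,tfc_ann_pred
1,80,15,50,1,-1,0,65.15,1.15,64.99,65.59,39.25,1.05,40.71,41.66
2,80,30,40,1,0,-1,61.56,0.52,62.3,62.6,40.25,0.98,39.28,39.25
3,60,45,60,0,1,1,63.55,1.15,64.13,64.89,44.8,0.56,45.29,44.57
4,60,30,50,0,0,0,75.26,1.01,75.7,76.88,58.32,0.28,57.41,57.95
5,60,30,50,0,0,0,75.56,0.89,75.77,76.85,57.01,1.15,57.41,57.2
6,60,30,50,0,0,0,76.15,0.69,75.87,75.32,59.4,0.89,57.41,57.69
7,80,45,50,1,1,0,61.95,1,61.57,61.6,41.53,0.79,41.65,41.25
8,60,15,60,0,-1,1,64.55,1.15,65.62,66.29,43.83,0.69,42.98,42.77
9,60,45,40,0,1,-1,63.35,0.69,62.97,62.57,42.67,1.09,43.52,44.09
10,40,15,50,-1,-1,0,60.92,0.59,61.21,61.55,37.62,1.1,37.5,38.83
11,60,15,40,0,-1,-1,66.39,1.01,65.8,66.33,43.77,0.99,43.28,42.62
12,40,30,60,-1,0,1,61.09,1.15,60.34,60.95,36.17,1.09,37.14,36.99
13,40,45,50,-1,1,0,60.23,0.79,60.38,61.75,40.56,1,39.1,39.56
14,60,30,50,0,0,0,76.65,0.49,75.17,76.6,56.32,1.02,57.41,58.25
15,60,30,50,0,0,0,75.25,0.89,75.77,76.05,56.01,0.58,57.41,57.85
16,40,30,40,-1,0,-1,60.89,0.92,61.1,61.59,38.79,0.65,39.41,40.66
17,80,30,60,1,0,1,64.15,1.09,64.03,65.6,43.64,0.45,43.03,44.25
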