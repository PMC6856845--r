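"technology","holdout_assay","method","subset","n","TP","FP","TN","FN","mcc","recall","precision","auc","excluded_reason"
"AlphaScreen","AlphaScreen_P1","bsf","all",36,0,0,26,10,0,0,,0.778846153846154,
"AlphaScreen","AlphaScreen_P1","pains","all",36,4,0,26,6,0.570087712549569,0.4,1,0.7,
"AlphaScreen","AlphaScreen_P1","bsf","set_a",7,0,0,2,5,0,0,,0.75,
"AlphaScreen","AlphaScreen_P1","pains","set_a",7,0,0,2,5,0,0,,0.5,
"AlphaScreen","AlphaScreen_P1","bsf","set_b",29,0,0,24,5,0,0,,0.654166666666667,
"AlphaScreen","AlphaScreen_P1","pains","set_b",29,4,0,24,1,0.876356092008266,0.8,1,0.9,
"AlphaScreen","AlphaScreen_P2","bsf","all",39,0,0,29,10,0,0,,0.717241379310345,
"AlphaScreen","AlphaScreen_P2","pains","all",39,3,1,28,7,0.382144583578808,0.3,0.75,0.632758620689655,
"AlphaScreen","AlphaScreen_P2","bsf","set_a",5,0,0,1,4,0,0,,0.875,
"AlphaScreen","AlphaScreen_P2","pains","set_a",5,1,0,1,3,0.25,0.25,1,0.625,
"AlphaScreen","AlphaScreen_P2","bsf","set_b",34,0,0,28,6,0,0,,0.5625,
"AlphaScreen","AlphaScreen_P2","pains","set_b",34,2,1,27,4,0.400012800614433,0.333333333333333,0.666666666666667,0.648809523809524,
"AlphaScreen","AlphaScreen_P3","bsf","all",39,0,0,28,11,0,0,,0.706168831168831,
"AlphaScreen","AlphaScreen_P3","pains","all",39,4,2,26,7,0.364447148062397,0.363636363636364,0.666666666666667,0.646103896103896,
"AlphaScreen","AlphaScreen_P3","bsf","set_a",8,0,0,3,5,0,0,,0.766666666666667,
"AlphaScreen","AlphaScreen_P3","pains","set_a",8,1,0,3,4,0.29277002188456,0.2,1,0.6,
"AlphaScreen","AlphaScreen_P3","bsf","set_b",31,0,0,25,6,0,0,,0.546666666666667,
"AlphaScreen","AlphaScreen_P3","pains","set_b",31,3,2,23,3,0.451152370644843,0.5,0.6,0.71,
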