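variant,tm_mean,tm_sd,rh25_mean,rh25_sd,rh37_mean,rh37_sd
212579,67.8,0.0,6.52,0.02,5.54,0.15
UCA,71.4,0.0,6.28,0.05,NA,NA
"212579 T40_H_N, I29_L_V, T40_L_A, V108_L_G",71.9,0.2,6.11,0.02,4.79,0.03
"212579 T40_H_N, I53_H_V, H113_H_Y",71.2,0.2,6.32,0.04,5.05,0.04
"212579 T40_H_N, I53_H_V",70.5,0.1,6.03,0.12,4.86,0.13
"212579 T40_H_N",70.2,0.2,6.07,0.02,4.89,0.02
"212579 I53_H_V, I29_L_V, T40_L_A, V108_L_G",68.3,0.2,6.67,0.02,5.24,0.02
"212579 I53_H_V",67.2,0.1,6.20,0.04,5.05,0.08
"212579 I29_L_V, T40_L_A, V108_L_G",66.2,0.0,6.53,0.02,5.05,0.01
"212579 E38_H_S",66.2,0.0,6.49,0.02,5.05,0.02
"212579 G62_H_S",65.7,0.1,6.46,0.06,5.20,0.03
"212579 E38_H_S, G62_H_S",68.3,0.2,6.37,0.02,4.92,0.01
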