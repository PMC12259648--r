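variant,ka_1e5,kd_1e4,KD_nM
212579,4.4,1.4,0.32
UCA,0.6,5.1,8.5
"212579 T40_H_N",3.2,1.6,0.49
"212579 I53_H_V",4.2,1.3,0.31
"212579 H113_H_Y",2.6,3.6,1.4
"212579 T40_H_N, I53_H_V",26,1.4,0.56
"212579 T40_H_N, I53_H_V, H113_H_Y",1.6,1.4,0.92
"212579 I29_L_V, T40_L_A, V108_L_G",2.3,3.5,1.5
"212579 I53_H_V, I29_L_V, T40_L_A, V108_L_G",2.2,3.3,1.5
"212579 T40_H_N, I29_L_V, T40_L_A, V108_L_G",1.2,5.0,4.3
"212579 E38_H_S",2.8,27.3,9.9
"212579 G62_H_S",4.2,1.1,0.27
"212579 E38_H_S, G62_H_S",1.3,26.2,19.6
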