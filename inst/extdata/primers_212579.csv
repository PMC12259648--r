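substitution,forward,reverse
T40_H_N,GCTCCTACGAGATGAACTGGGTTAGACAGG,CGCCTGTCTAACCCAGTTCATCTCGTAGGAGC
I53_H_V,AAAGGCCTGGAATGGGTCAGCTACATCAGCA,TGCTGATGTAGCTGACCCATTCCAGGCCTTT
H113_H_Y,GATAACTACTATTACTACGGCATGGATGTGT,ACACATCCATGCCGTAGTAATAGTAGTTATC
I29_L_V+T40_L_A,AGAGCTTCTCAGAGCGTCAGCAGCAGCTACCTGGCATGGTATCAGCAAA,TTTGCTGATACCATGCCAGGTAGCTGCTGCTGACGCTCTGAGAAGCTCT
V108_L_G,ACTGCCAGCAGTACGGGTCCTCCCTGATCAC,GTGATCAGGGAGGACCCGTACTGCTGGCAGT
E38_H_S,ACCTTCAGCTCCTACTCGATGACCTGGGTTAGC,TAACCCAGGTCATCGAGTAGGAGCTGAAGGT
G62_H_S,TACATCAGCAGCTCTAGCAGCACAATCTACT,AGTAGATTGTGCTGCTAGAGCTGCTGATGTA
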