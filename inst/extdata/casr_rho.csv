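snp,snp_1,snp_2,snp_3,snp_4,snp_5,snp_6
snp_1,1.000,0.070,0.094,-0.172,0.079,-0.104
snp_2,0.070,1.000,-0.050,0.081,-0.080,-0.014
snp_3,0.094,-0.050,1.000,-0.306,0.349,-0.134
snp_4,-0.172,0.081,-0.306,1.000,-0.129,0.446
snp_5,0.079,-0.080,0.349,-0.129,1.000,-0.289
snp_6,-0.104,-0.014,-0.134,0.446,-0.289,1.000
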