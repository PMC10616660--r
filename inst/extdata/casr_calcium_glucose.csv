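snp,bx,bxse,by,byse
snp_1,0.00625,0.00233,0.02805,0.0122
snp_2,0.00590,0.00338,0.00953,0.0198
snp_3,0.01822,0.00318,0.03646,0.0173
snp_4,0.00598,0.00233,0.01049,0.0119
snp_5,0.00825,0.00229,0.02357,0.0122
snp_6,0.00651,0.00352,0.00204,0.0179
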