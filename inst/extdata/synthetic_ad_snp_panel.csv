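snp_id,risk_allele,frequency,odds_ratio
snp_01,A,0.1,2.5
snp_02,C,0.121,1.22
snp_03,G,0.142,0.81
snp_04,T,0.163,1.17
snp_05,A,0.184,0.88
snp_06,C,0.206,1.15
snp_07,G,0.227,1.1
snp_08,T,0.248,0.92
snp_09,A,0.269,1.12
snp_10,C,0.29,1.08
snp_11,G,0.311,0.9
snp_12,T,0.332,1.18
snp_13,A,0.353,1.06
snp_14,C,0.374,0.93
snp_15,G,0.396,1.14
snp_16,T,0.417,1.09
snp_17,A,0.438,0.87
snp_18,C,0.459,1.11
snp_19,G,0.48,1.2
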