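temperature_C,cmc1_mM,cmc1_sd_mM,cmc2_mM,cmc2_sd_mM,cmc_mix_mM,cmc_mix_sd_mM,cmc_mix_tens_mM,cmc_mix_tens_sd_mM,alpha1
0,9.00,0.16,10.00,0.12,4.09,0.12,4.19,0.05,0.5
5,9.50,0.13,10.23,0.14,4.01,0.12,4.09,0.06,0.5
10,10.00,0.18,10.47,0.17,4.01,0.12,4.12,0.06,0.5
15,10.50,0.17,10.82,0.13,4.17,0.13,4.22,0.07,0.5
20,11.00,0.21,11.31,0.18,4.12,0.12,4.23,0.08,0.5
25,11.50,0.23,11.98,0.21,4.07,0.12,4.20,0.06,0.5
30,12.00,0.25,12.40,0.22,4.21,0.13,4.33,0.07,0.5
35,12.50,0.26,13.11,0.26,4.40,0.13,4.54,0.08,0.5
40,13.00,0.29,13.58,0.31,4.54,0.14,4.70,0.09,0.5
45,13.50,0.28,14.03,0.31,4.76,0.14,4.90,0.11,0.5
50,14.00,0.35,14.78,0.35,6.78,0.20,7.02,0.16,0.5
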