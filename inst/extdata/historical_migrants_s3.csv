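"",JPA_Am,JPA_SP,JTR_Go,JTR_NI,JTR_Tr
JPA_Am,NA,2.03,1.62,1.68,1.72
JPA_SP,13.02,NA,1.80,3.91,2.53
JTR_Go,18.14,3.90,NA,3.97,13.80
JTR_NI,18.09,6.03,6.65,NA,2.10
JTR_Tr,12.93,3.20,1.71,10.36,NA
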