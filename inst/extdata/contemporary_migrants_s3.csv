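"",JPA_Am,JPA_SP,JTR_Go,JTR_NI,JTR_Tr
JPA_Am,NA,12,6,3,5
JPA_SP,8,NA,0,1,2
JTR_Go,0,0,NA,2,2
JTR_NI,0,2,2,NA,3
JTR_Tr,4,1,1,2,NA
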