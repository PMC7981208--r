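"",JPA_Am,JPA_SP,JTR_Go,JTR_NI,JTR_Tr
JPA_Am,NA,19,2,4,1
JPA_SP,11,NA,1,1,3
JTR_Go,2,0,NA,4,2
JTR_NI,1,0,0,NA,4
JTR_Tr,0,1,1,5,NA
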