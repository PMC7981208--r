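"",JPA_Am,JPA_SP,JTR_Go,JTR_NI,JTR_Tr
JPA_Am,NA,11,9,0,2
JPA_SP,11,NA,1,0,0
JTR_Go,0,0,NA,0,5
JTR_NI,0,0,3,NA,3
JTR_Tr,0,2,3,2,NA
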