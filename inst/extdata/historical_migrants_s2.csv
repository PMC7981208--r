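"",JPA_Am,JPA_SP,JTR_Go,JTR_NI,JTR_Tr
JPA_Am,NA,2.95,1.81,2.50,2.28
JPA_SP,22.24,NA,4.34,2.77,5.46
JTR_Go,17.63,3.15,NA,11.99,5.78
JTR_NI,39.42,5.63,9.15,NA,6.40
JTR_Tr,30.74,10.67,7.24,4.17,NA
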