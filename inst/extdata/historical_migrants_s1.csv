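"",JPA_Am,JPA_SP,JTR_Go,JTR_NI,JTR_Tr
JPA_Am,NA,2.37,1.27,1.77,1.72
JPA_SP,14.88,NA,2.24,1.49,4.57
JTR_Go,25.31,10.17,NA,7.91,4.42
JTR_NI,27.82,3.35,1.95,NA,6.52
JTR_Tr,10.98,2.80,1.94,3.05,NA
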