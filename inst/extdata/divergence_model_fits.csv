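scenario,K,logL,AIC
PSC,8,-2216,4448
SI,3,-2387,4780
SC,6,-2892,5796
IM,5,-3039,6089
PAM,6,-4497,9007
AM,6,-4266,8544
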