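version,MDC_95,MCID 0.20 SD,MCID 0.33 SD,MCID 0.50 SD
8,1.25,0.25,0.41,0.63
10,1.03,0.22,0.37,0.56
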