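name,forward,reverse,source
EM-PC2consFD/EM-PC3consRD,TCACMATYCATGGCCTATGG,AWCTRCCRTGYTTGTTCCATTC,"Sutherland et al. 2004"
Pru-C2/Amy-C5,CTATGGCCAAGTAATTATTCAAACC,TACCACTTCATGTAACAACTGAG,"Tao et al. 1999"
Pru-C2/PCE-R,CTATGGCCAAGTAATTATTCAAACC,TGTTTGTTCCATTCGCCTTCCC,"Tao et al. 1999; Wu et al. 2009"
AS1II/Amy-C5,TATTTTCAATTTGTGCAATGG,CAAAATACCACTTCATGTAACAAC,"Tamura et al. 2000"
PaConsII-F/PaConsII-R,GGCCAAGTAATTATTCAAACC,CATAACAAARTACCACTTCATGTAAC,"Sonneveld et al. 2003"
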