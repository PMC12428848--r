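name,pattern,max_mismatch
C2,TIHGLWPSN[YF],1
C3,GEWNKHGTC[SA],1
RC4,IPRLRNELD[KR],1
C5,GSCYFDKIL[NQ],1
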