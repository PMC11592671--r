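name,kind,start,end,sequence,crm1_class,variant,mutant_sequence
NLS_1,NLS,213,224,KTKMQKKLERRK,,K213E,ETKMQKKLERRK
NLS_2,NLS,436,447,RKKILGAVRRRR,,R447W,RKKILGAVRRRW
NES_1,NES,181,195,LTSSTLSRRLQHLAL,1a,L195E,LTSSTLSRRLQHLAE
NES_2,NES,235,249,EDGRKSARSLSGLQL,1b,L249E,EDGRKSARSLSGLQE
NES_3,NES,406,420,ALLRQEKIDLEALML,2,,
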