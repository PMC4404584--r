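dataset,NB,TAN,KDB,FKBN
dataset01,4,2,2,2
dataset02,4,3,1.5,1.5
dataset03,4,2,2,2
dataset04,4,1.5,3,1.5
dataset05,4,2,2,2
dataset06,4,3,1.5,1.5
dataset07,2.5,2.5,2.5,2.5
dataset08,2.5,2.5,2.5,2.5
dataset09,2.5,2.5,2.5,2.5
dataset10,2.5,2.5,2.5,2.5
dataset11,2.5,2.5,2.5,2.5
dataset12,2.5,2.5,2.5,2.5
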