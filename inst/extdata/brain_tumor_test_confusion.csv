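class,AST,CAR,EPE,GAN,GER,GLI,GRA,MED,MEN,NEU,NOR,OLI,PAP,SCH,TUB
AST,78,0,0,0,0,0,0,0,0,0,0,0,0,0,0
CAR,0,37,0,0,0,0,0,0,1,0,0,0,0,0,0
EPE,0,0,18,0,0,0,0,0,0,0,0,0,0,0,0
GAN,0,0,0,5,0,0,0,0,0,0,1,0,0,0,0
GER,0,0,0,0,12,0,0,0,0,0,0,0,0,0,0
GLI,0,0,0,0,0,24,0,0,0,0,0,0,0,0,0
GRA,0,0,0,0,0,0,11,0,0,0,0,0,0,0,0
MED,0,0,0,0,0,0,0,25,0,0,0,0,0,0,0
MEN,0,0,0,0,0,0,0,0,62,0,0,0,0,0,0
NEU,1,0,0,0,0,0,0,0,0,38,0,0,0,0,0
NOR,0,0,0,0,0,0,0,0,0,0,55,0,0,0,0
OLI,0,0,0,0,0,0,0,0,0,0,0,27,0,0,0
PAP,0,0,0,0,0,0,0,0,0,0,0,0,12,0,0
SCH,0,0,0,0,0,0,0,0,1,0,0,0,0,80,0
TUB,0,0,0,0,0,0,0,0,0,0,0,0,0,0,20
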