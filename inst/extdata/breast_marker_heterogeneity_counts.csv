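marker,LumA_het,LumA_n,LumB_het,LumB_n,HER2+_het,HER2+_n,TNBC_het,TNBC_n,published_percent
Rictor,7,9,5,9,6,8,3,7,60
p-S6,8,9,8,10,8,8,8,10,87
p-mTOR,9,10,10,10,7,9,6,10,84
GLUT1,4,10,6,10,9,9,7,10,67
LDHA,2,10,4,10,3,9,2,10,28
HK2,6,9,9,10,7,8,6,10,76
PFKP,2,9,4,10,6,8,5,8,49
ASCT2,8,10,10,10,8,8,9,10,92
GLS,1,7,2,9,3,7,4,8,32
FASN,4,10,6,10,5,9,4,9,45
CPT1A,6,9,1,10,5,9,4,9,43
ACC,4,8,6,10,6,6,3,8,59
ACSS2,2,10,1,10,4,9,2,10,23
ATPb,0,8,1,8,3,7,1,8,16
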