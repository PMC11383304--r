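phoneme,class,syllabic,sonorant,continuant
AA,vowel,1,1,1
AE,vowel,1,1,1
AH,vowel,1,1,1
AO,vowel,1,1,1
AW,vowel,1,1,1
AY,vowel,1,1,1
EH,vowel,1,1,1
ER,vowel,1,1,1
EY,vowel,1,1,1
IH,vowel,1,1,1
IY,vowel,1,1,1
OW,vowel,1,1,1
OY,vowel,1,1,1
UH,vowel,1,1,1
UW,vowel,1,1,1
L,approximant,0,1,1
R,approximant,0,1,1
W,approximant,0,1,1
Y,approximant,0,1,1
M,nasal,0,1,0
N,nasal,0,1,0
NG,nasal,0,1,0
F,fricative,0,0,1
V,fricative,0,0,1
TH,fricative,0,0,1
DH,fricative,0,0,1
S,fricative,0,0,1
Z,fricative,0,0,1
SH,fricative,0,0,1
ZH,fricative,0,0,1
HH,fricative,0,0,1
P,stop,0,0,0
B,stop,0,0,0
T,stop,0,0,0
D,stop,0,0,0
K,stop,0,0,0
G,stop,0,0,0
CH,affricate,0,0,0
JH,affricate,0,0,0
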