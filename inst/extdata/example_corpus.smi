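Oc1ccccc1NONNO
c1ccccc1OONO
NOONNO
Oc1ccccc1
NOCCCCNC(O)
CNON
ONCOC(ON)NC(CN)O
NNC(O)OCCONCC
ONNCCONCNC
OONCCNOONNCCC
OOCNON
ONN
NNCc1ccccc1NNOOC
ONCO
C(NO)O
OOON
ONCONC
NC(NO)OCCCONC
NNc1ccccc1C(O)O
C(O)O
COc1ccccc1ONO
NNOONOC1CCCCC1O
NONNOOC1CCCCC1
NNOC1CCCCC1NNN
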