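# Genes implicated in hereditary cholestatic syndromes (illustrative list;
# supply a full database snapshot for real analyses)
ATP8B1
ABCB11
ABCB4
TJP2
BAAT
CYP7A1
CYP7B1
HSD3B7
AKR1D1
NR1H4
JAG1
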