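# Bile acid and bile salt metabolism (illustrative)
AKR1C1
AKR1D1
RXRA
CYP7A1
CYP7B1
CYP8B1
CYP27A1
HSD3B7
SLC27A5
BAAT
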