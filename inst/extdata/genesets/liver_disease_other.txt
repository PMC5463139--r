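# Other liver-disease genes, incl. drug metabolism and cirrhosis (illustrative)
KRT8
KRT18
CYP2C19
CYP2C9
NAT2
SERPINA1
HFE
ATP7B
FAM104B
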