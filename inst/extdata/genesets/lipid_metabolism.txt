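# Lipid and phospholipid metabolism (illustrative)
PEMT
APOB
MTTP
LMF2
PNPLA3
TM6SF2
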