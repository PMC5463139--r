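# Bile secretion and transport (illustrative)
ABCC4
ABCB11
ABCB4
ABCC2
ABCC3
SLC10A1
SLC51A
SLC51B
ATP8B1
AQP8
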