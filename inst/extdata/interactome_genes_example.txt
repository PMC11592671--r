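# Example nuclear-interactome gene list for the karyopherin screen
KPNB1
IPO4
IPO5
IPO7
IPO8
IPO9
IPO11
IPO13
XPO1
XPO5
XPOT
PRPF31
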