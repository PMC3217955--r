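g02_p001
g02_p002
g02_p003
g02_p004
g02_p005
g02_p006
g02_p007
g02_p008
g02_p009
g02_p010
g02_p011
g02_p012
g02_p013
g02_p014
g02_p015
g02_p016
g02_p017
g02_p018
g02_p019
g02_p020
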