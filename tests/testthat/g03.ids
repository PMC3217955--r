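g03_p001
g03_p002
g03_p003
g03_p004
g03_p005
g03_p006
g03_p007
g03_p008
g03_p009
g03_p010
g03_p011
g03_p012
g03_p013
g03_p014
g03_p015
g03_p016
g03_p017
g03_p018
g03_p019
g03_p020
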