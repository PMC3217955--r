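# synthetic study set (planted carriers + background)
g01_p002
g01_p003
g01_p005
g01_p007
g01_p009
g01_p012
g01_p016
g01_p017
g01_p018
g01_p019
g01_p004
g01_p008
g01_p010
g01_p011
g01_p013
g01_p015
g01_p020
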