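GO:0000002
GO:0000003
GO:0000017
GO:0000018
GO:0000032
GO:0000033
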