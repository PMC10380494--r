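class	count
single	1967
duplicated	42
fragmented	48
missing	64
complete	2009
total	2121
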