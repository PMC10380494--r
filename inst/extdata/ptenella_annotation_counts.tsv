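database	genes
GO	10761
KEGG	11435
KOG	19251
Swissprot	19449
Pfam	22815
Nr	31202
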