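quantity	value
contig_total_bp	231191648
scaffold_total_bp	231208648
chromosome_total_bp	207446423
total_genes	32088
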