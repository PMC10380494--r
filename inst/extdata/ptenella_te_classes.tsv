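class	type	subclass	length_bp
Retrotransposons	Ty1/Copia	LTR	8454829
Retrotransposons	Ty3/Gypsy	LTR	18247107
Retrotransposons	unknown	LTR	15756928
DNA_transposons	CACTA	TIR	1845596
DNA_transposons	Mutator	TIR	7818414
DNA_transposons	PIF/Harbinger	TIR	4181524
DNA_transposons	Tc1/Mariner	TIR	278071
DNA_transposons	hAT	TIR	3345229
DNA_transposons	Helitron	Non-TIR	7038992
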