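position	ref_aa	alt_aa	source	phenotype
738	I	T	HGMD	PAIS
752	W	R	HGMD	CAIS
807	C	Y	HGMD	PAIS
813	L	F	HGMD	CAIS
600	R	K	COSMIC	prostate cancer
615	C	*	HGMD	CAIS
300	L	P	HGMD	partial androgen insensitivity
880	V	M	polymorphism	none
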