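id	role	structure	racemic	notes
methanesulfonyl	cap	C[SH:1](=O)=O	FALSE	mesyl; attaches through sulfur (sulfonamide)
acetyl	cap	C[CH:1]=O	FALSE	attaches through the carbonyl carbon (amide)
methyl	cap	[CH4:1]	FALSE	N-methylation
phenyl	cap	[cH:1]1ccccc1	FALSE	N-arylation
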