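id	role	structure	racemic	notes
pyrimidin-5-yl	fragment	[cH:1]1cncnc1	FALSE	from 5-bromopyrimidine
pyridin-3-yl	fragment	[cH:1]1cccnc1	FALSE	from 3-bromopyridine
pyrazol-4-yl	fragment	[cH:1]1c[nH]nc1	FALSE	from 4-bromo-1H-pyrazole
6-aminopyridin-3-yl	fragment	[cH:1]1ccc(N)nc1	FALSE	from 5-bromopyridin-2-amine
4-methoxyphenyl	fragment	[cH:1]1ccc(OC)cc1	FALSE	from 4-bromoanisole
2-methoxyphenyl	fragment	[cH:1]1ccccc1OC	FALSE	from 2-bromoanisole
3-carbamoylphenyl	fragment	[cH:1]1cccc(C(N)=O)c1	FALSE	from 3-bromobenzamide
4-cyanophenyl	fragment	[cH:1]1ccc(C#N)cc1	FALSE	from 4-bromobenzonitrile
7-azaindol-5-yl	fragment	[cH:1]1cc2cc[nH]c2nc1	FALSE	from 5-bromo-7-azaindole
indazol-5-yl	fragment	[cH:1]1cc2cn[nH]c2cc1	FALSE	from 5-bromo-1H-indazole
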