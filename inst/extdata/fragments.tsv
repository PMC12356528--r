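id	role	structure	racemic	notes
pyrimidin-5-yl	fragment	[cH:1]1cncnc1	FALSE	from 5-bromopyrimidine (a FragLite); the default fragment for virtual elaboration
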