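id	role	structure	racemic	notes
1a	building_block	[NH:2]1[C@@:1]2([H])[C@H](C2)CC1	TRUE	2,3-fused pyrrolidine-cyclopropane; handle on the junction carbon alpha to N (C1 and N2 directly bonded)
1b	building_block	[NH:2]1CC[C@]2([C@:1]([H])([H])C2)CC1	TRUE	spiro cyclopropane at piperidine C4; handle on a cyclopropane methylene
1c	building_block	[NH:2]1C[C@]2([C@:1]([H])([H])C2)C1	TRUE	spiro cyclopropane at azetidine C3; handle on a cyclopropane methylene
1d	building_block	[NH:2]1[C@]2([C@@:1]([H])([H])C2)CCC1	TRUE	spiro cyclopropane at pyrrolidine C2; handle anti to N (diastereomer of 1e; syn/anti assignment is a package convention)
1e	building_block	[NH:2]1[C@]2([C@:1]([H])([H])C2)CCC1	TRUE	spiro cyclopropane at pyrrolidine C2; handle syn to N (diastereomer of 1d)
1f	building_block	[NH:2]1[C@@H]2C[C@]3([C@@:1]([H])([H])C3)C[C@H]1CC2	TRUE	tropane: spiro cyclopropane at C3 of 8-azabicyclo[3.2.1]octane, cyclopropane anti to the ethano bridge
1g	building_block	[NH:2]1C[C@H]2[C@H]([C@@:1]2([H])[H])CC1	TRUE	3,4-fused piperidine-cyclopropane; handle exo on the cyclopropane apex
1h	building_block	[NH:2]1C[C@H]2[C@H]([C@@:1]2([H])[H])C1	FALSE	3,4-fused pyrrolidine-cyclopropane; handle exo on the apex; meso
1i	building_block	[NH:2]1[C@H]2[C@H]([C@@:1]2([H])[H])CCC1	TRUE	2,3-fused piperidine-cyclopropane; handle exo on the cyclopropane apex
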