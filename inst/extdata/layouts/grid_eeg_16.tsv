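channel	x	y	kind	group
E1	0	0	eeg	G1
E2	1	0	eeg	G2
E3	2	0	eeg	G3
E4	3	0	eeg	G4
E5	0	1	eeg	G5
E6	1	1	eeg	G6
E7	2	1	eeg	G7
E8	3	1	eeg	G8
E9	0	2	eeg	G9
E10	1	2	eeg	G10
E11	2	2	eeg	G11
E12	3	2	eeg	G12
E13	0	3	eeg	G13
E14	1	3	eeg	G14
E15	2	3	eeg	G15
E16	3	3	eeg	G16
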