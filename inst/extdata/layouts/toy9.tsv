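channel	x	y	kind	group
x1	0	0	planar	L1
y1	0	0	planar	L1
c1	0	0	combined	L1
x2	1	0	planar	L2
y2	1	0	planar	L2
c2	1	0	combined	L2
x3	2	0	planar	L3
y3	2	0	planar	L3
c3	2	0	combined	L3
x4	0	1	planar	L4
y4	0	1	planar	L4
c4	0	1	combined	L4
x5	1	1	planar	L5
y5	1	1	planar	L5
c5	1	1	combined	L5
x6	2	1	planar	L6
y6	2	1	planar	L6
c6	2	1	combined	L6
x7	0	2	planar	L7
y7	0	2	planar	L7
c7	0	2	combined	L7
x8	1	2	planar	L8
y8	1	2	planar	L8
c8	1	2	combined	L8
x9	2	2	planar	L9
y9	2	2	planar	L9
c9	2	2	combined	L9
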