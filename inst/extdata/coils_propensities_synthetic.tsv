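residue	a	b	c	d	e	f	g
A	1.7	1.2	1.2	1.6	1.2	1.2	1.2
R	0.8	1.4	1.4	0.8	1.6	1.3	1.6
N	0.6	1.0	1.0	0.6	1.0	1.0	1.0
D	0.5	1.1	1.1	0.5	1.1	1.1	1.1
C	0.8	0.6	0.6	0.8	0.6	0.6	0.6
Q	0.9	1.5	1.5	0.9	1.5	1.5	1.5
E	0.9	1.8	1.8	0.9	1.9	1.6	1.9
G	0.3	0.3	0.3	0.3	0.3	0.3	0.3
H	0.8	0.9	0.9	0.8	0.9	0.9	0.9
I	2.6	0.8	0.8	2.0	0.8	0.8	0.8
L	3.2	1.2	1.2	3.0	1.2	1.2	1.2
K	0.8	1.6	1.6	0.9	1.8	1.5	1.8
M	2.2	1.0	1.0	2.0	1.0	1.0	1.0
F	1.6	0.7	0.7	1.4	0.7	0.7	0.7
P	0.05	0.05	0.05	0.05	0.05	0.05	0.05
S	0.7	0.9	0.9	0.7	0.9	0.9	0.9
T	0.7	0.9	0.9	0.7	0.9	0.9	0.9
W	0.6	0.6	0.6	0.6	0.6	0.6	0.6
Y	0.8	0.7	0.7	0.8	0.7	0.7	0.7
V	2.2	0.8	0.8	1.7	0.8	0.8	0.8
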