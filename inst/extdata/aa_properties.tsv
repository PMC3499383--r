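residue	hydropathy	volume	charge	polarity	helix
A	1.8	88.6	0	8.1	1.42
C	2.5	108.5	0	5.5	0.70
D	-3.5	111.1	-1	13.0	1.01
E	-3.5	138.4	-1	12.3	1.51
F	2.8	189.9	0	5.2	1.13
G	-0.4	60.1	0	9.0	0.57
H	-3.2	153.2	0.1	10.4	1.00
I	4.5	166.7	0	5.2	1.08
K	-3.9	168.6	1	11.3	1.16
L	3.8	166.7	0	4.9	1.21
M	1.9	162.9	0	5.7	1.45
N	-3.5	114.1	0	11.6	0.67
P	-1.6	112.7	0	8.0	0.57
Q	-3.5	143.8	0	10.5	1.11
R	-4.5	173.4	1	10.5	0.98
S	-0.8	89.0	0	9.2	0.77
T	-0.7	116.1	0	8.6	0.83
V	4.2	140.0	0	5.9	1.06
W	-0.9	227.8	0	5.4	1.08
Y	-1.3	193.6	0	6.2	0.69
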