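code	sigma	charge	mass
A	5	0	71.08
R	6.6	1	156.19
N	5.7	0	114.1
D	5.6	-1	115.09
C	5.5	0	103.14
Q	6	0	128.13
E	5.9	-1	129.12
G	4.5	0	57.05
H	6.1	0.5	137.14
I	6.2	0	113.16
L	6.2	0	113.16
K	6.4	1	128.17
M	6.2	0	131.19
F	6.4	0	147.18
P	5.6	0	97.12
S	5.2	0	87.08
T	5.6	0	101.1
W	6.8	0	186.21
Y	6.5	0	163.18
V	5.9	0	99.13
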