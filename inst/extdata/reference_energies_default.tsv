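aa	energy
A	1.33
C	-1.42
D	-1.63
E	-1.82
F	1.15
G	0.59
H	0.43
I	2.32
K	-0.72
L	1.87
M	1.45
N	-1.08
P	-0.64
Q	-1.26
R	-0.96
S	-0.28
T	0.12
V	2.06
W	0.98
Y	0.68
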