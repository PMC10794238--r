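# Binary hydrophobicity classification of the 20 amino acids
# (1 = hydrophobic). Documented stand-in keyed to the strongly hydrophobic
# class of contact-potential work; override via the `hydrophobic_set`
# argument of hydrophobic_preference().
aa	hydrophobic
A	1
C	1
F	1
I	1
L	1
M	1
V	1
W	1
Y	1
R	0
N	0
D	0
Q	0
E	0
G	0
H	0
K	0
P	0
S	0
T	0
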