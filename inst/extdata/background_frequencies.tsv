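# Background amino-acid frequencies: average composition of proteins in a
# large non-redundant sequence database (documented stand-in table,
# renormalized at load time). Override via the `background` argument of
# estimate_frequencies().
aa	freq
A	0.0789
R	0.0554
N	0.0404
D	0.0541
C	0.0151
Q	0.0393
E	0.0672
G	0.0708
H	0.0228
I	0.0593
L	0.0965
K	0.0580
M	0.0241
F	0.0397
P	0.0482
S	0.0663
T	0.0541
W	0.0110
Y	0.0292
V	0.0686
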