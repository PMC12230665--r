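aa	name3	residue_mass	charge	polar	aromatic	helix_breaker	beta_propensity	hydropathy
A	Ala	71.08	0	0	0	0	0.83	1.8
R	Arg	156.19	1	1	0	0	0.93	-4.5
N	Asn	114.10	0	1	0	0	0.89	-3.5
D	Asp	115.09	-1	1	0	0	0.54	-3.5
C	Cys	103.14	0	1	0	0	1.19	2.5
Q	Gln	128.13	0	1	0	0	1.10	-3.5
E	Glu	129.12	-1	1	0	0	0.37	-3.5
G	Gly	57.05	0	0	0	1	0.75	-0.4
H	His	137.14	1	1	1	0	0.87	-3.2
I	Ile	113.16	0	0	0	0	1.60	4.5
L	Leu	113.16	0	0	0	0	1.30	3.8
K	Lys	128.17	1	1	0	0	0.74	-3.9
M	Met	131.20	0	0	0	0	1.05	1.9
F	Phe	147.18	0	0	1	0	1.38	2.8
P	Pro	97.12	0	0	0	1	0.55	-1.6
S	Ser	87.08	0	1	0	0	0.75	-0.8
T	Thr	101.10	0	1	0	0	1.19	-0.7
W	Trp	186.21	0	0	1	0	1.37	-0.9
Y	Tyr	163.18	0	1	1	0	1.47	-1.3
V	Val	99.13	0	0	0	0	1.70	4.2
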