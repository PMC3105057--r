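# Reduced amino-acid alphabets: alphabet name, group symbol, member residues.
# A is the identity alphabet (20 singleton groups, symbol = residue).
# H (hydrophobicity), V (normalized van der Waals volume), Z (polarizability)
# and P (polarity) are the three-class physicochemical descriptors of
# Dubchak-style sequence feature extraction.
# F (4 groups), S (7) and E (8) are physicochemical partitions into four,
# seven and eight classes; their exact memberships are approximations (see
# package documentation) and every alphabet here can be overridden via
# alphabet_overrides().
alphabet	symbol	residues
A	A	A
A	C	C
A	D	D
A	E	E
A	F	F
A	G	G
A	H	H
A	I	I
A	K	K
A	L	L
A	M	M
A	N	N
A	P	P
A	Q	Q
A	R	R
A	S	S
A	T	T
A	V	V
A	W	W
A	Y	Y
H	1	RKEDQN
H	2	GASTPHY
H	3	CLVIMFW
V	1	GASTCPD
V	2	NVEQIL
V	3	MHKFRYW
Z	1	GASDT
Z	2	CPNVEQIL
Z	3	KMHFRYW
P	1	LIFWCMVY
P	2	PATGS
P	3	HQRKNED
F	1	DEHKR
F	2	CNQST
F	3	FWY
F	4	AGILMPV
S	1	AGV
S	2	ILFP
S	3	YMTS
S	4	HNQW
S	5	RK
S	6	DE
S	7	C
E	1	AG
E	2	C
E	3	DE
E	4	FWY
E	5	H
E	6	ILMV
E	7	KR
E	8	NPQST
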