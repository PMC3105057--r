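# PDB-derived ice-binding protein reference set: id, label, homology subset.
# Subsets group sequences so that no cross-validation fold is tested on
# sequences homologous to its training folds.
1c3y	AFP	1
1c89	AFP	2
3nla	AFP	2
1ucs	AFP	2
1ops	AFP	2
1kde	AFP	2
1ame	AFP	2
1msi	AFP	2
1b7i	AFP	2
1b7j	AFP	2
1b7k	AFP	2
1ekl	AFP	2
1gzi	AFP	2
1hg7	AFP	2
1jab	AFP	2
1msj	AFP	2
2ame	AFP	2
2jia	AFP	2
2msi	AFP	2
2msj	AFP	2
2spg	AFP	2
3ame	AFP	2
3msi	AFP	2
4ame	AFP	2
4msi	AFP	2
5msi	AFP	2
6ame	AFP	2
6msi	AFP	2
7ame	AFP	2
7msi	AFP	2
8ame	AFP	2
8msi	AFP	2
9ame	AFP	2
9msi	AFP	2
1ezg	AFP	3
1wfa	AFP	4
1j5b	AFP	4
1y03	AFP	4
1eww	AFP	5
1l0s	AFP	5
1m8n	AFP	5
2pne	AFP	6
2py2	AFP	7
2afp	AFP	7
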