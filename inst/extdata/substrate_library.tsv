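# Proteinogenic / NRPS-relevant amino-acid substrates with isomeric SMILES.
# Used as the default substrate library of the synthetic fixture generator,
# so fingerprinting in tests is chemically meaningful.
name	smiles
tryptophan	C1=CC=C2C(=C1)C(=CN2)C[C@@H](C(=O)O)N
phenylalanine	N[C@@H](Cc1ccccc1)C(=O)O
serine	N[C@@H](CO)C(=O)O
valine	CC(C)[C@@H](C(=O)O)N
leucine	CC(C)C[C@@H](C(=O)O)N
alanine	C[C@@H](C(=O)O)N
glutamate	N[C@@H](CCC(=O)O)C(=O)O
ornithine	NCCC[C@@H](C(=O)O)N
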