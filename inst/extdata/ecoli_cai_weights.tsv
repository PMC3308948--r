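# Relative adaptiveness (w) of each sense codon in the Escherichia coli high-expression
# reference gene set, for Codon Adaptation Index calculation.
# Source: Sharp & Li (1987) NAR 15:1281-1295, values as distributed with CodonW.
# Stop codons omitted. One w = 1 (optimal) codon per amino acid.
codon	amino_acid	w
GCA	A	0.586
GCC	A	0.122
GCG	A	0.424
GCT	A	1.000
TGC	C	1.000
TGT	C	0.500
GAC	D	1.000
GAT	D	0.434
GAA	E	1.000
GAG	E	0.259
TTC	F	1.000
TTT	F	0.296
GGA	G	0.010
GGC	G	0.724
GGG	G	0.019
GGT	G	1.000
CAC	H	1.000
CAT	H	0.291
ATA	I	0.003
ATC	I	1.000
ATT	I	0.185
AAA	K	1.000
AAG	K	0.253
CTA	L	0.007
CTC	L	0.037
CTG	L	1.000
CTT	L	0.042
TTA	L	0.020
TTG	L	0.020
ATG	M	1.000
AAC	N	1.000
AAT	N	0.051
CCA	P	0.135
CCC	P	0.012
CCG	P	1.000
CCT	P	0.070
CAA	Q	0.124
CAG	Q	1.000
AGA	R	0.004
AGG	R	0.002
CGA	R	0.004
CGC	R	0.356
CGG	R	0.004
CGT	R	1.000
AGC	S	0.410
AGT	S	0.085
TCA	S	0.077
TCC	S	0.744
TCG	S	0.017
TCT	S	1.000
ACA	T	0.076
ACC	T	1.000
ACG	T	0.099
ACT	T	0.965
GTA	V	0.495
GTC	V	0.066
GTG	V	0.221
GTT	V	1.000
TGG	W	1.000
TAC	Y	1.000
TAT	Y	0.239
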