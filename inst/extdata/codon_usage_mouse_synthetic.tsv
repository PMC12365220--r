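codon	amino_acid	family_fraction	per_thousand
GCC	A	0.3812316716	26
GCT	A	0.2932551320	20
GCA	A	0.2316715543	15.8
GCG	A	0.0938416422	6.4
TGC	C	0.5189873418	12.3
TGT	C	0.4810126582	11.4
GAC	D	0.5531914894	26
GAT	D	0.4468085106	21
GAG	E	0.5933734940	39.4
GAA	E	0.4066265060	27
TTC	F	0.5589743590	21.8
TTT	F	0.4410256410	17.2
GGC	G	0.3281733746	21.2
GGA	G	0.2600619195	16.8
GGG	G	0.2352941176	15.2
GGT	G	0.1764705882	11.4
CAC	H	0.5907335907	15.3
CAT	H	0.4092664093	10.6
ATC	I	0.4966887417	22.5
ATT	I	0.3399558499	15.4
ATA	I	0.1633554084	7.4
AAG	K	0.6054054054	33.6
AAA	K	0.3945945946	21.9
CTG	L	0.3872549020	39.5
CTC	L	0.2049019608	20.9
CTT	L	0.1313725490	13.4
TTG	L	0.1313725490	13.4
CTA	L	0.0794117647	8.1
TTA	L	0.0656862745	6.7
ATG	M	1.0000000000	22.8
AAC	N	0.5654596100	20.3
AAT	N	0.4345403900	15.6
CCT	P	0.3061564060	18.4
CCC	P	0.3028286190	18.2
CCA	P	0.2878535774	17.3
CCG	P	0.1031613977	6.2
CAG	Q	0.7396963124	34.1
CAA	Q	0.2603036876	12
AGG	R	0.2210144928	12.2
AGA	R	0.2192028986	12.1
CGG	R	0.1847826087	10.2
CGC	R	0.1702898551	9.4
CGA	R	0.1195652174	6.6
CGT	R	0.0851449275	4.7
AGC	S	0.2382103990	19.7
TCC	S	0.2188633615	18.1
TCT	S	0.1958887545	16.2
AGT	S	0.1535671100	12.7
TCA	S	0.1426844015	11.8
TCG	S	0.0507859734	4.2
ACC	T	0.3499079190	19
ACA	T	0.2946593002	16
ACT	T	0.2523020258	13.7
ACG	T	0.1031307551	5.6
GTG	V	0.4588045234	28.4
GTC	V	0.2487883683	15.4
GTT	V	0.1728594507	10.7
GTA	V	0.1195476575	7.4
TGG	W	1.0000000000	12.5
TAC	Y	0.5689045936	16.1
TAT	Y	0.4310954064	12.2
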