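anticodon	copy_number
AGC	11
TGC	5
GCA	4
GTC	16
TTC	14
GAA	10
GCC	16
CAT	10
GTG	7
AAT	13
TAT	2
TTT	7
CTT	14
AAG	7
CAA	10
TAA	3
TAG	2
GAT	15
ATT	0
TGG	10
TTG	9
ACG	6
TCT	11
CCT	1
CCG	1
AGA	11
GCT	5
CGA	3
TGA	3
AGT	11
TGT	2
AAC	14
TAC	2
CCA	6
GTA	8
GGT	4
GGC	9
GGA	7
TCC	3
CGG	2
CTG	1
CGC	1
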