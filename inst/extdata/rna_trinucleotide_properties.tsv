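# aptgen property table, schema v1
# columns: unit<TAB>property<TAB>value (raw; standardized at load time)
# k-mer values are means of mononucleotide scales over constituent bases
# id: rna_trinucleotide_v1
unit	property	value
AAA	nmp_mass	347.2
AAC	nmp_mass	339.2
AAG	nmp_mass	352.533333333333
AAU	nmp_mass	339.533333333333
ACA	nmp_mass	339.2
ACC	nmp_mass	331.2
ACG	nmp_mass	344.533333333333
ACU	nmp_mass	331.533333333333
AGA	nmp_mass	352.533333333333
AGC	nmp_mass	344.533333333333
AGG	nmp_mass	357.866666666667
AGU	nmp_mass	344.866666666667
AUA	nmp_mass	339.533333333333
AUC	nmp_mass	331.533333333333
AUG	nmp_mass	344.866666666667
AUU	nmp_mass	331.866666666667
CAA	nmp_mass	339.2
CAC	nmp_mass	331.2
CAG	nmp_mass	344.533333333333
CAU	nmp_mass	331.533333333333
CCA	nmp_mass	331.2
CCC	nmp_mass	323.2
CCG	nmp_mass	336.533333333333
CCU	nmp_mass	323.533333333333
CGA	nmp_mass	344.533333333333
CGC	nmp_mass	336.533333333333
CGG	nmp_mass	349.866666666667
CGU	nmp_mass	336.866666666667
CUA	nmp_mass	331.533333333333
CUC	nmp_mass	323.533333333333
CUG	nmp_mass	336.866666666667
CUU	nmp_mass	323.866666666667
GAA	nmp_mass	352.533333333333
GAC	nmp_mass	344.533333333333
GAG	nmp_mass	357.866666666667
GAU	nmp_mass	344.866666666667
GCA	nmp_mass	344.533333333333
GCC	nmp_mass	336.533333333333
GCG	nmp_mass	349.866666666667
GCU	nmp_mass	336.866666666667
GGA	nmp_mass	357.866666666667
GGC	nmp_mass	349.866666666667
GGG	nmp_mass	363.2
GGU	nmp_mass	350.2
GUA	nmp_mass	344.866666666667
GUC	nmp_mass	336.866666666667
GUG	nmp_mass	350.2
GUU	nmp_mass	337.2
UAA	nmp_mass	339.533333333333
UAC	nmp_mass	331.533333333333
UAG	nmp_mass	344.866666666667
UAU	nmp_mass	331.866666666667
UCA	nmp_mass	331.533333333333
UCC	nmp_mass	323.533333333333
UCG	nmp_mass	336.866666666667
UCU	nmp_mass	323.866666666667
UGA	nmp_mass	344.866666666667
UGC	nmp_mass	336.866666666667
UGG	nmp_mass	350.2
UGU	nmp_mass	337.2
UUA	nmp_mass	331.866666666667
UUC	nmp_mass	323.866666666667
UUG	nmp_mass	337.2
UUU	nmp_mass	324.2
AAA	purine	1
AAC	purine	0.666666666666667
AAG	purine	1
AAU	purine	0.666666666666667
ACA	purine	0.666666666666667
ACC	purine	0.333333333333333
ACG	purine	0.666666666666667
ACU	purine	0.333333333333333
AGA	purine	1
AGC	purine	0.666666666666667
AGG	purine	1
AGU	purine	0.666666666666667
AUA	purine	0.666666666666667
AUC	purine	0.333333333333333
AUG	purine	0.666666666666667
AUU	purine	0.333333333333333
CAA	purine	0.666666666666667
CAC	purine	0.333333333333333
CAG	purine	0.666666666666667
CAU	purine	0.333333333333333
CCA	purine	0.333333333333333
CCC	purine	0
CCG	purine	0.333333333333333
CCU	purine	0
CGA	purine	0.666666666666667
CGC	purine	0.333333333333333
CGG	purine	0.666666666666667
CGU	purine	0.333333333333333
CUA	purine	0.333333333333333
CUC	purine	0
CUG	purine	0.333333333333333
CUU	purine	0
GAA	purine	1
GAC	purine	0.666666666666667
GAG	purine	1
GAU	purine	0.666666666666667
GCA	purine	0.666666666666667
GCC	purine	0.333333333333333
GCG	purine	0.666666666666667
GCU	purine	0.333333333333333
GGA	purine	1
GGC	purine	0.666666666666667
GGG	purine	1
GGU	purine	0.666666666666667
GUA	purine	0.666666666666667
GUC	purine	0.333333333333333
GUG	purine	0.666666666666667
GUU	purine	0.333333333333333
UAA	purine	0.666666666666667
UAC	purine	0.333333333333333
UAG	purine	0.666666666666667
UAU	purine	0.333333333333333
UCA	purine	0.333333333333333
UCC	purine	0
UCG	purine	0.333333333333333
UCU	purine	0
UGA	purine	0.666666666666667
UGC	purine	0.333333333333333
UGG	purine	0.666666666666667
UGU	purine	0.333333333333333
UUA	purine	0.333333333333333
UUC	purine	0
UUG	purine	0.333333333333333
UUU	purine	0
AAA	wc_hbonds	2
AAC	wc_hbonds	2.33333333333333
AAG	wc_hbonds	2.33333333333333
AAU	wc_hbonds	2
ACA	wc_hbonds	2.33333333333333
ACC	wc_hbonds	2.66666666666667
ACG	wc_hbonds	2.66666666666667
ACU	wc_hbonds	2.33333333333333
AGA	wc_hbonds	2.33333333333333
AGC	wc_hbonds	2.66666666666667
AGG	wc_hbonds	2.66666666666667
AGU	wc_hbonds	2.33333333333333
AUA	wc_hbonds	2
AUC	wc_hbonds	2.33333333333333
AUG	wc_hbonds	2.33333333333333
AUU	wc_hbonds	2
CAA	wc_hbonds	2.33333333333333
CAC	wc_hbonds	2.66666666666667
CAG	wc_hbonds	2.66666666666667
CAU	wc_hbonds	2.33333333333333
CCA	wc_hbonds	2.66666666666667
CCC	wc_hbonds	3
CCG	wc_hbonds	3
CCU	wc_hbonds	2.66666666666667
CGA	wc_hbonds	2.66666666666667
CGC	wc_hbonds	3
CGG	wc_hbonds	3
CGU	wc_hbonds	2.66666666666667
CUA	wc_hbonds	2.33333333333333
CUC	wc_hbonds	2.66666666666667
CUG	wc_hbonds	2.66666666666667
CUU	wc_hbonds	2.33333333333333
GAA	wc_hbonds	2.33333333333333
GAC	wc_hbonds	2.66666666666667
GAG	wc_hbonds	2.66666666666667
GAU	wc_hbonds	2.33333333333333
GCA	wc_hbonds	2.66666666666667
GCC	wc_hbonds	3
GCG	wc_hbonds	3
GCU	wc_hbonds	2.66666666666667
GGA	wc_hbonds	2.66666666666667
GGC	wc_hbonds	3
GGG	wc_hbonds	3
GGU	wc_hbonds	2.66666666666667
GUA	wc_hbonds	2.33333333333333
GUC	wc_hbonds	2.66666666666667
GUG	wc_hbonds	2.66666666666667
GUU	wc_hbonds	2.33333333333333
UAA	wc_hbonds	2
UAC	wc_hbonds	2.33333333333333
UAG	wc_hbonds	2.33333333333333
UAU	wc_hbonds	2
UCA	wc_hbonds	2.33333333333333
UCC	wc_hbonds	2.66666666666667
UCG	wc_hbonds	2.66666666666667
UCU	wc_hbonds	2.33333333333333
UGA	wc_hbonds	2.33333333333333
UGC	wc_hbonds	2.66666666666667
UGG	wc_hbonds	2.66666666666667
UGU	wc_hbonds	2.33333333333333
UUA	wc_hbonds	2
UUC	wc_hbonds	2.33333333333333
UUG	wc_hbonds	2.33333333333333
UUU	wc_hbonds	2
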