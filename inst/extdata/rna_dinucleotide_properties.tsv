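# aptgen property table, schema v1
# columns: unit<TAB>property<TAB>value (raw; standardized at load time)
# k-mer values are means of mononucleotide scales over constituent bases
# id: rna_dinucleotide_v1
unit	property	value
AA	nmp_mass	347.2
AC	nmp_mass	335.2
AG	nmp_mass	355.2
AU	nmp_mass	335.7
CA	nmp_mass	335.2
CC	nmp_mass	323.2
CG	nmp_mass	343.2
CU	nmp_mass	323.7
GA	nmp_mass	355.2
GC	nmp_mass	343.2
GG	nmp_mass	363.2
GU	nmp_mass	343.7
UA	nmp_mass	335.7
UC	nmp_mass	323.7
UG	nmp_mass	343.7
UU	nmp_mass	324.2
AA	purine	1
AC	purine	0.5
AG	purine	1
AU	purine	0.5
CA	purine	0.5
CC	purine	0
CG	purine	0.5
CU	purine	0
GA	purine	1
GC	purine	0.5
GG	purine	1
GU	purine	0.5
UA	purine	0.5
UC	purine	0
UG	purine	0.5
UU	purine	0
AA	wc_hbonds	2
AC	wc_hbonds	2.5
AG	wc_hbonds	2.5
AU	wc_hbonds	2
CA	wc_hbonds	2.5
CC	wc_hbonds	3
CG	wc_hbonds	3
CU	wc_hbonds	2.5
GA	wc_hbonds	2.5
GC	wc_hbonds	3
GG	wc_hbonds	3
GU	wc_hbonds	2.5
UA	wc_hbonds	2
UC	wc_hbonds	2.5
UG	wc_hbonds	2.5
UU	wc_hbonds	2
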