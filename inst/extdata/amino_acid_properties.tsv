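# aptgen property table, schema v1
# columns: unit<TAB>property<TAB>value (raw; standardized at load time)
# k-mer values are means of mononucleotide scales over constituent bases
# id: amino_acid_v1
unit	property	value
A	hydropathy	1.8
C	hydropathy	2.5
D	hydropathy	-3.5
E	hydropathy	-3.5
F	hydropathy	2.8
G	hydropathy	-0.4
H	hydropathy	-3.2
I	hydropathy	4.5
K	hydropathy	-3.9
L	hydropathy	3.8
M	hydropathy	1.9
N	hydropathy	-3.5
P	hydropathy	-1.6
Q	hydropathy	-3.5
R	hydropathy	-4.5
S	hydropathy	-0.8
T	hydropathy	-0.7
V	hydropathy	4.2
W	hydropathy	-0.9
Y	hydropathy	-1.3
A	hydrophilicity	-0.5
C	hydrophilicity	-1
D	hydrophilicity	3
E	hydrophilicity	3
F	hydrophilicity	-2.5
G	hydrophilicity	0
H	hydrophilicity	-0.5
I	hydrophilicity	-1.8
K	hydrophilicity	3
L	hydrophilicity	-1.8
M	hydrophilicity	-1.3
N	hydrophilicity	0.2
P	hydrophilicity	0
Q	hydrophilicity	0.2
R	hydrophilicity	3
S	hydrophilicity	0.3
T	hydrophilicity	-0.4
V	hydrophilicity	-1.5
W	hydrophilicity	-3.4
Y	hydrophilicity	-2.3
A	sidechain_mass	15
C	sidechain_mass	47.1
D	sidechain_mass	59
E	sidechain_mass	73.1
F	sidechain_mass	91.1
G	sidechain_mass	1
H	sidechain_mass	81.1
I	sidechain_mass	57.1
K	sidechain_mass	72.2
L	sidechain_mass	57.1
M	sidechain_mass	75.1
N	sidechain_mass	58.1
P	sidechain_mass	42.1
Q	sidechain_mass	72.1
R	sidechain_mass	101.2
S	sidechain_mass	31
T	sidechain_mass	45.1
V	sidechain_mass	43.1
W	sidechain_mass	130.2
Y	sidechain_mass	107.1
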