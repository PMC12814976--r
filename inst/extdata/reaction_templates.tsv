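id	smirks	description
amide	[C:1](=[O:2])!@[N:3]>>[C:1](=[O:2])[*:4].[N:3][*:5]	Amide coupling: cleave the acyclic C(=O)-N bond
ester	[C:1](=[O:2])!@[O;D2:3]>>[C:1](=[O:2])[*:4].[O:3][*:5]	Esterification: cleave the acyclic acyl C-O bond
alkyl_ether	[C;!$(C=O):1]!@[O;D2:2][C;!$(C=O)]>>[C:1][*:3].[O:2][*:4]	Williamson ether synthesis: cleave an acyclic sp3 C-O ether bond
aryl_ether	[c:1]!@[O;D2:2]>>[c:1][*:3].[O:2][*:4]	Aryl ether formation: cleave the acyclic aromatic C-O bond
sulfonamide	[S:1](=[O:2])(=[O:3])!@[N:4]>>[S:1](=[O:2])(=[O:3])[*:5].[N:4][*:6]	Sulfonamide formation: cleave the acyclic S(=O)(=O)-N bond
aryl_amine	[c:1]!@[N;!$(N=*):2]>>[c:1][*:3].[N:2][*:4]	Buchwald-Hartwig amination: cleave the acyclic aromatic C-N bond
alkyl_amine	[C;!$(C=O):1]!@[N;!$(N=*):2]>>[C:1][*:3].[N:2][*:4]	Reductive amination: cleave an acyclic sp3 C-N bond
benzylic	[c:1]!@[C;!$(C=*):2]>>[c:1][*:3].[C:2][*:4]	Aryl-alkyl coupling: cleave the acyclic aromatic C - sp3 C bond
thioether	[C:1]!@[S;D2:2]>>[C:1][*:3].[S:2][*:4]	Thioether formation: cleave an acyclic C-S bond
aryl_halide	[c:1]!@[F,Cl,Br:2]>>[c:1][*:3].[*:2]	Halogenation: cleave the aromatic C-halogen bond
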