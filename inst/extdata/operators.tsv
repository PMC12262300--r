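# Minimal enzymatic reaction operators: one atom-mapped core per line,
# optionally followed by a tab and a name. Patterns are concrete mapped
# cores; unchanged atoms act as matching context only.
[O:3]=[C:2][O:4].[OH2:6]>>[O:3]=[C:2][OH:6].[OH:4]	ester_hydrolysis
[C:2]=[O:3]>>[CH:2][OH:3]	ketone_reduction
[C:1][C:4](=[O:5])[OH:6]>>[CH:1].[O:5]=[C:4]=[O:6]	decarboxylation
[O:3]=[C:2][N:4].[OH2:6]>>[O:3]=[C:2][OH:6].[NH:4]	amide_hydrolysis
[CH:2][OH:3]>>[C:2]=[O:3]	alcohol_oxidation
[O:3]=[C:2][OH:4].[OH:6]>>[O:3]=[C:2][O:6].[OH2:4]	esterification
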