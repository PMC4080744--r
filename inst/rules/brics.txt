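# BRICS-style cleavage rules, re-encoded (simplified) as mapped SMARTS
# within this package's SMARTS subset. Environment constraints of the
# published scheme that need recursive SMARTS are approximated with
# degree/ring primitives.
ester_acyl	[C;X3:1](=O)[O;X2:2][C]
amide_acyl	[C;X3:1](=O)[N:2]
amine_aliphatic	[C;X4:1][N;X3:2]([C;X4])[C;X4]
ether	[C;X4:1][O;X2:2][C;X4]
olefin	[C;X3:1]=[C;X3:2]
aromatic_C_aliphatic_C	[c:1][C;X4:2]
aromatic_N_aliphatic_C	[n:1][C;X4:2]
biaryl	[c:1]-[c:2]
sulfonyl	[S;X4:1](=O)(=O)[C:2]
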