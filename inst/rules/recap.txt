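# RECAP-style retrosynthetic cleavage rules, re-encoded as mapped SMARTS
# within this package's SMARTS subset (no recursive SMARTS). The mapped
# atoms :1 and :2 flank the bond that is cut. These encodings approximate
# the published bond classes; the X/R constraints stand in for recursive
# environment checks.
amide	[C;X3:1](=O)[N;X3:2]
ester	C(=O)[O:1][C:2]
amine	[N;X3:1]([C;X4])([C;X4])[C;X4:2]
urea	[N;X3:1][C;X3:2](=O)[N;X3]
ether	[C;X4:1][O;X2:2][C;X4]
olefin	[C;X3:1]=[C;X3:2]
quaternary_N	[N;+:1][C;X4:2]
aromatic_N_aliphatic_C	[n:1][C;X4:2]
lactam_N_aliphatic_C	[N;X3;R:1][C;X4;!R:2]
biaryl	[c:1]-[c:2]
sulfonamide	[N;X3:1][S;X4:2](=O)=O
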