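# CCQ-style cleavage rules (common cleavable-bond queries), re-encoded as
# mapped SMARTS within this package's SMARTS subset.
amide	[C;X3:1](=O)[N:2]
ester	C(=O)[O:1][C:2]
amine	[C;X4:1][N;X3:2]
ether	[C;X4:1][O;X2:2][C;X4]
thioether	[C;X4:1][S;X2:2][C;X4]
sulfonamide	[N;X3:1][S;X4:2](=O)=O
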