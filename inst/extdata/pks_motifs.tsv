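# Packaged Type I PKS signature motifs (name<TAB>pattern<TAB>alphabet).
# Grammar: uppercase letters are literals, 'x' matches any residue,
# '[...]' encloses a strict alternative set. Users may copy and extend.
name	pattern	alphabet
KS_DTACSS	DTACSS	protein
AT_GHSLG	GHSLG	protein
KR_motif	GxGxxGxxxA	protein
DH_motif	HxxxGxxxx	protein
ER_motif	LxHxxxGGVG	protein
NTERM_ExExGYLG	ExExGYLG	protein
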