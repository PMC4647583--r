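# Synthetic GrsA-type A-domain reference: 8 annotated binding-pocket positions
# (1-based reference coordinates). The residues at these positions spell DAWTIAAI.
position	residue
235	D
236	A
239	W
278	T
299	I
301	A
322	A
330	I
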