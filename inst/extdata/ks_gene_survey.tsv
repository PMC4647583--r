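# KS-domain-containing gene models of the S. minutum genome survey:
# gene id, protein length (aa), domain-architecture string, scaffold.
# symbB1.v1.2.012436.t1 (the 10,601-aa hybrid NRPS-PKS) has no printed
# architecture string; its row is a reconstruction of the published
# 8-module schematic (3 NRPS incl. one C-HxxPF-A NRPS-like assembly,
# 5 PKS, terminal thioesterase).
gene_id	total_aa	domain_string	scaffold
symbB1.v1.2.000535.t1	4838	KS	31.1
symbB1.v1.2.001307.t1	797	KS	57.1
symbB1.v1.2.001928.t1	1164	KS	55.1
symbB1.v1.2.002919.t1	1105	KS	160.1
symbB1.v1.2.008781.t1	2107	DH-KR-PP-PP-KS-DH	514.1
symbB1.v1.2.008782.t1	1848	KR-PP-KS-KR-PP-KS	514.1
symbB1.v1.2.012436.t1	10601	C-A-PP-KS-AT-DH-KR-PP-KS-KR-MT-PP-KS-DH-PP-C-A-PP-C-HXXPF-A-KS-KR-PP-KS-PP-TE	860.1
symbB1.v1.2.013880.t1	1071	KS	991.1
symbB1.v1.2.015788.t2	920	KR-PP-KS-AT	1186.1
symbB1.v1.2.015789.t1	1216	KR-PP-KS	1186.1
symbB1.v1.2.015790.t1	427	KS	1186.1
symbB1.v1.2.015913.t1	1671	KS	1171.1
symbB1.v1.2.017689.t1	2261	KS	1368.1
symbB1.v1.2.019160.t1	1068	KS	1555.1
symbB1.v1.2.020241.t1	656	KS	1693.1
symbB1.v1.2.022565.t1	1547	KS	2011.1
symbB1.v1.2.027279.t1	615	KS	2789.1
symbB1.v1.2.027671.t1	957	AM-PP-KS-AT	2857.1
symbB1.v1.2.028834.t1	2431	KS	3094.1
symbB1.v1.2.030435.t1	481	KS-AT	3430.1
symbB1.v1.2.036002.t1	2987	AM-PP-KS-KR-DH	4981.1
symbB1.v1.2.036410.t1	3519	AM-KS-KR-PP-KS-DH-KR-PP-KS	5132.1
symbB1.v1.2.037839.t1	604	KS	5703.1
symbB1.v1.2.039083.t1	980	AT-KS-PP	6338.1
symbB1.v1.2.040026.t1	582	KS	6945.1
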