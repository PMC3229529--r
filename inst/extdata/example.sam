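@HD	VN:1.3	SO:coordinate
@SQ	SN:ref	LN:45
r001	163	ref	7	30	8M2I4M1D3M	=	37	39	TTAGATAAAGGATACTG	*
r002	0	ref	7	30	3S6M1P1I4M	*	0	0	AAAAGATAAGGATA	*
r002	0	ref	9	30	5S6M	*	0	0	GCCTAAGCTAA	*	NM:i:1
r003	0	ref	9	30	6M14N5M	*	0	0	ATAGCTTCAGC	*
r003	16	ref	9	30	6H5M	*	0	0	TAGGC	*	NM:i:0
r004	16	ref	16	30	6M	*	0	0	ATAGCT	*
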