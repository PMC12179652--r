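species	region	weights	consensus	period	copy_number	percent_matches	percent_indels
H. rubroreticulatus	ITS2	2-7-7	TTCCCCTAGTAACTGCGAGTGAAGCGGGAAGAGCTCAAATTTCGAATCTGGCGGTCTCTTTGGCCG	66	2	100	0
H. bubalinus	ITS1	2-7-7	AC	2	7-13	100	0
H. bubalinus	ITS2	2-7-7	GGGACTCGAGCGAAGGGTCGGCTTAGCTATTAGTTGGTCGTGAGGCCAGCGAACGCGGTCGGGCTGTGGGTCTCGAGCTTCA	82	2.8	81-86	5-7
H. bubalinus	ITS2	2-3-5	TTCGGGACTCGAGCGAAGGGTCGGCTTAGCTATTAGTTGGTCGTGAGGCCAGCGAACGCGGTCGGGCTGGGTCGTCGAG	79	2.9-3.1	80-82	6-8
H. amygdalinus	ITS2	2-7-7	GGTTGGCTTAGCTATTAGTCGGTCGTGAGGCCGACGAACGCGGTCGACTTGGAAAG	56	2.9	88	2
H. rufosquamosus	ITS2	2-3-5	GGGTCGGCTTAGCTATTAGTTGGTCGTGAGGCCGACGAACGCGGGTCGACTCGGCAAAACGTT	63	2.1	90	4
Hortiboletus sp. 5	ITS2	2-7-7	GGGACTCGAGCGAAGGTCGGCTTAGCTATTAGTTGGTCGTGAGGCCAGCGAACGCGGTCGGGCTGGGTTTCGAGTTCAG	79	3	85	5
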