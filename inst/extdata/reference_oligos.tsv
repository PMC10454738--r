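name	sequence	reference_g_score
TERRA	GGGTTAGGGTTAGGGTTAGGG	72
SNHG20	GGGTTTGGGCTGGGGCCTGGG	72
MEG3	GGGAAATTCTCAGGAGGGGGACCTGGGCCAAGGG	64
LINP1	GGGGTAGGAGAGGGTATGGGGACCAGGGCACTCTGTAAGGG	69
CRNDE_R1	GGGCTAGGGCCTGGGCCTCGGG	71
CRNDE_R2	GGGTGTCGGGGTTCGGGGCGGG	72
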