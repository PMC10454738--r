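gene_symbol	label
H19	upregulated
MEG3	downregulated
NEAT1	upregulated
SNHG20	upregulated
GHET1	upregulated
CRNDE	upregulated
HAGLR	upregulated
NORAD	upregulated
CASC2	downregulated
SLC16A1-AS1	differential
MALAT1	upregulated
FEZF1-AS1	upregulated
EWSAT1	downregulated
LINP1	upregulated
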