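symbol	compartments
FMR2	cytoplasm
hnRNP A2	nucleoplasm;nucleus
Nucleolin	nucleoplasm;nucleus
DHX36	nucleoplasm;cytoplasm
SRSF1	nucleoplasm;nucleus
SRSF9	nucleoplasm;nucleus
TLS	nucleoplasm;nucleus
TRF2	nucleoplasm;nucleus
PTEN	nucleoplasm;cytosol
SMAD4	nucleoplasm;cytosol
TP53	nucleoplasm
CDKN2A	nucleoli
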