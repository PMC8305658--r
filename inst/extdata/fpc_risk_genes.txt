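# FPC risk genes considered in tier-2 triage; one symbol per line.
# Editable: seeded with established pancreatic-cancer predisposition genes
# and the low-frequency candidates reported in FPC sequencing studies.
ATM
POLQ
BUB1B
CPA1
FANCC
FANCG
BRCA1
BRCA2
PALB2
CDKN2A
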