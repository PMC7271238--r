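AKT1
EIF4EBP1
FOXO1
IRS1
MTOR
MAPK3
PIK3CA
PTEN
PDK1
RPS6KB1
RPS6
RHEB
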