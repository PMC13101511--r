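name,molecular_weight
pyrene,202.25
DIPA,242.23
1H2N,188.18
salicylic,138.12
phthalic,166.13
protocatechuic,154.12
fluorene,166.22
phenanthrene,178.23
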