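aplasia
bowing
broad
calcification
cupping
demineralization
dysplasia
erosion
flared
flattening
fragmentation
fusion
irregular
irregularity
lucency
osteolysis
osteopenia
sclerosis
short
shortening
thickening
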