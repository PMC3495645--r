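apophyses
clavicles
cortex
epiphyses
femoral necks
femur
iliac wings
long bones
metacarpals
metaphyses
metatarsals
pelvis
radial club hand
radius
ribs
skull
tibia
trabeculae
ulna
vertebrae
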