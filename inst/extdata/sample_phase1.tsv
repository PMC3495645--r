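# syn00001
sclerosis	Q-B
epiphyses	A-B
of	A-I
the	A-I
femoral	A-I
necks	A-I

# syn00002
widening	Q-B
iliac	A-B
wings	A-I

# syn00003
lucency	Q-B
central	A-B
pelvis	A-I
with	C-B
sclerosis	Q-B

# syn00004
dysplasia	Q-B
bilateral	A-B
ulna	A-I

# syn00005
broadening	Q-B
epiphyses	A-B
of	A-I
the	A-I
radius	A-I

# syn00006
osteopenia	Q-B
tibia	A-B

# syn00007
severe	Q-B
broad	Q-I
focal	Q-B
broadening	Q-I
proximal	A-B
or	A-I
radial	A-I
apophyses	A-I
of	A-I
the	A-I
phalanges	A-I

# syn00008
cupping	Q-B
thickening	Q-B
anterior	A-B
metaphyses	A-I
of	A-I
the	A-I
iliac	A-I
wings	A-I

# syn00009
irregularity	Q-B
widening	Q-B
epiphyses	A-B
of	A-I
the	A-I
metacarpals	A-I

# syn00010
cupping	Q-B
metaphyses	A-B
of	A-I
the	A-I
phalanges	A-I

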