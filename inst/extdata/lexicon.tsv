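metaphyses	metaphysis	noun
epiphyses	epiphysis	noun
diaphyses	diaphysis	noun
metadiaphyses	metadiaphysis	noun
apophyses	apophysis	noun
trabeculae	trabecula	noun
vertebrae	vertebra	noun
ribs	rib	noun
clavicles	clavicle	noun
scapulae	scapula	noun
phalanges	phalanx	noun
metacarpals	metacarpal	noun
metatarsals	metatarsal	noun
bones	bone	noun
necks	neck	noun
wings	wing	noun
femur	femur	noun
tibia	tibia	noun
radius	radius	noun
ulna	ulna	noun
humerus	humerus	noun
pelvis	pelvis	noun
skull	skull	noun
cortex	cortex	noun
hand	hand	noun
irregular	irregular	adj
streaky	streaky	adj
long	long	adj
short	short	adj
broad	broad	adj
dense	dense	adj
proximal	proximal	adj
distal	distal	adj
lateral	lateral	adj
medial	medial	adj
central	central	adj
severe	severe	adj
mild	mild	adj
flared	flare	verb
flaring	flare	verb
cupping	cup	verb
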