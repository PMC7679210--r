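# abbreviation / variant mappings: surface TAB canonical
tkr	total knee replacement
thr	total hip replacement
physio	physiotherapy
mri	magnetic resonance imaging
acl	anterior cruciate ligament
pcl	posterior cruciate ligament
mcl	medial collateral ligament
lcl	lateral collateral ligament
oa	osteoarthritis
ra	rheumatoid arthritis
rom	range of motion
gp	general practitioner
nsaid	anti inflammatory
usg	ultrasound
xray	x ray
x-ray	x ray
f/u	follow up
appt	appointment
hx	history
rx	treatment
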