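# toy concept lexicon: term TAB concept_id TAB semtype
# concept ids follow the CUI format; ids for terms not shown in the
# published markup examples are synthetic placeholders
painkiller	C0002771	phsu
analgesic	C0002771	phsu
pain relief	C0002771	phsu
oedema	C0013604	patf
edema	C0013604	patf
swelling	C0013604	patf
tear	C3203359	inpo
rupture	C3203359	inpo
total knee replacement	C0086511	topp
knee arthroplasty	C0086511	topp
knee prosthesis	C0086511	topp
knee pain	C2220048	sosy
bilateral knee pain	C2220048	sosy
medial joint line tenderness	C0576135	sosy
tender medial joint line	C0576135	sosy
mcmurray test	C3669149	diap
meniscus tear	C0240126	inpo
ligament tear	C0262560	inpo
anterior cruciate ligament	C0009952	bpoc
medial collateral ligament	C0222004	bpoc
lateral collateral ligament	C0222005	bpoc
posterior cruciate ligament	C0009953	bpoc
meniscus	C0224498	bpoc
kneecap	C0030647	bpoc
patella	C0030647	bpoc
femur	C0015811	bpoc
tibia	C0040184	bpoc
cartilage	C0007301	bpoc
hip joint	C0019558	bpoc
knee joint	C0022745	bpoc
joint line	C0223889	bpoc
hoffa fat pad	C0223806	bpoc
baker cyst	C0004775	patf
popliteal cyst	C0031049	patf
osteoarthritis	C0029408	dsyn
arthritis	C0003864	dsyn
rheumatoid arthritis	C0003873	dsyn
bursitis	C0006444	dsyn
tendinitis	C0039503	dsyn
tendinopathy	C0039503	dsyn
chondromalacia	C0008445	dsyn
effusion	C0013687	patf
instability	C0022408	sosy
locking	C0240099	sosy
crepitus	C0277964	sosy
stiffness	C0221170	sosy
hip pain	C0019559	sosy
back pain	C0004604	sosy
joint pain	C0003862	sosy
arthralgia	C0003862	sosy
physiotherapy	C0699718	topp
physical therapy	C0699718	topp
injection	C0021485	topp
steroid injection	C0149783	topp
arthroscopy	C0003904	diap
surgery	C0038895	topp
operation	C0038895	topp
hip replacement	C0019552	topp
total hip replacement	C0019552	topp
hip arthroplasty	C0019552	topp
magnetic resonance imaging	C0024485	diap
x ray	C0043299	diap
radiograph	C0043299	diap
ultrasound	C0041618	diap
paracetamol	C0000970	phsu
ibuprofen	C0020740	phsu
naproxen	C0027396	phsu
codeine	C0009214	phsu
opioid	C0242402	phsu
anti inflammatory	C0003209	phsu
weight loss	C1262477	fndg
obesity	C0028754	dsyn
diabetes	C0011849	dsyn
hypertension	C0020538	dsyn
depression	C0011570	dsyn
range of motion	C0080078	fndg
mobility	C0080078	fndg
walking	C0600108	dora
gait	C0016928	fndg
limp	C0023216	sosy
fall	C0000921	inpo
injury	C3263722	inpo
trauma	C3263722	inpo
sprain	C0038056	inpo
strain	C0080194	inpo
dislocation	C0012691	inpo
fracture	C0016658	inpo
twisting injury	C0433092	inpo
rugby	C0035096	dora
skiing	C0037447	dora
football	C0016517	dora
badminton	C0004717	dora
sport	C0038039	dora
ice hockey	C0019994	dora
basketball	C0004818	dora
netball	C0241405	dora
golf	C0018041	dora
tennis	C0039505	dora
swimming	C0039003	dora
cycling	C0004380	dora
squash	C0037391	dora
jogging	C0022400	dora
gym	C0222333	dora
dancing	C0011001	dora
gardening	C0017191	dora
bracing	C0006086	topp
knee brace	C0179330	topp
crutches	C0010392	medd
nutritionist	C0237064	prog
dietitian	C0237064	prog
orthopaedic surgeon	C0334918	prog
general practitioner	C0017319	prog
review appointment	C0185089	hlca
follow up	C0589120	hlca
discharge	C0030685	hlca
referral	C0034927	hlca
clinic	C0002424	hlca
quadriceps	C0034358	bpoc
hamstring	C0039248	bpoc
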