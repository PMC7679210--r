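# irregular English forms: inflected TAB lemma
feet	foot
teeth	tooth
knees	knee
men	man
women	woman
children	child
mice	mouse
geese	goose
people	person
was	be
were	be
is	be
are	be
been	be
am	be
has	have
had	have
having	have
does	do
did	do
done	do
goes	go
went	go
gone	go
saw	see
seen	see
came	come
taken	take
took	take
given	give
gave	give
felt	feel
found	find
left	leave
made	make
said	say
told	tell
worse	bad
worst	bad
better	good
best	good
criteria	criterion
diagnoses	diagnosis
prostheses	prosthesis
analyses	analysis
menisci	meniscus
bursae	bursa
injuries	injury
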