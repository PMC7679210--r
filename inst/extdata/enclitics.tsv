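# irregular enclitic expansions applied before the generic rules
won't	will not
can't	cannot
shan't	shall not
ain't	is not
it's	it is
he's	he is
she's	she is
that's	that is
there's	there is
what's	what is
who's	who is
let's	let us
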