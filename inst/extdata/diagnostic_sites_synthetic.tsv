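position	ref_base	hg_A	hg_B	hg_C	hg_D	hg_E
15401	C	T	C	C	C	C
15432	A	A	A	G	A	A
15460	T	T	T	T	C	T
15497	G	G	G	G	G	A
15521	C	T	C	C	C	C
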