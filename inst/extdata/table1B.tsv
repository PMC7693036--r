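entry	is_reference	r253	p253	r156	p156	r128	p128	r120	p120	r257	p257
ChR2	TRUE	D	253	D	156	C	128	R	120	K	257
KnRh3	FALSE	D	250	D	154	C	126	R	118	K	254
TsRh1	FALSE	D	236	D	139	C	111	R	103	K	240
GpRh1	FALSE	D	213	D	116	C	88	R	80	K	217
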