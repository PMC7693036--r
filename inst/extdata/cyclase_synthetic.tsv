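entry	is_reference	r45	p45	r89	p89	r101	p101	r145	p145	r149	p149
CyaRef	TRUE	D	45	D	89	E	101	N	145	R	149
Cop6	FALSE	D	52	D	97	E	110	N	151	R	155
Cop5	FALSE	S	50	D	94	-	NA	-	NA	-	NA
Vop5	FALSE	A	48	D	92	-	NA	-	NA	-	NA
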