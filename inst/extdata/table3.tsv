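entry	is_reference	residue	residue_name	polarity_printed	shift_printed	group_label	flag
GreenPR	TRUE	L	Leucine	Non-Polar	Green	Green PR
BluePR	TRUE	Q	Glutamine	Polar	Blue	Blue PR
KnRh3	FALSE	I	Isoleucine	Non-polar	Green	KnRh3, TsRh1 and GpRh3
TsRh1	FALSE	I	Isoleucine	Non-polar	Green	KnRh3, TsRh1 and GpRh3
GpRh3	FALSE	I	Isoleucine	Non-polar	Green	KnRh3, TsRh1 and GpRh3	duplicate
Cop8	FALSE	I	Isoleucine	Non-polar	Green	Cop8-12, GpRh2, ApRh1, AsRh2
Cop9	FALSE	I	Isoleucine	Non-polar	Green	Cop8-12, GpRh2, ApRh1, AsRh2
Cop10	FALSE	I	Isoleucine	Non-polar	Green	Cop8-12, GpRh2, ApRh1, AsRh2
Cop11	FALSE	I	Isoleucine	Non-polar	Green	Cop8-12, GpRh2, ApRh1, AsRh2
Cop12	FALSE	I	Isoleucine	Non-polar	Green	Cop8-12, GpRh2, ApRh1, AsRh2
GpRh2	FALSE	I	Isoleucine	Non-polar	Green	Cop8-12, GpRh2, ApRh1, AsRh2
ApRh1	FALSE	I	Isoleucine	Non-polar	Green	Cop8-12, GpRh2, ApRh1, AsRh2
AsRh2	FALSE	I	Isoleucine	Non-polar	Green	Cop8-12, GpRh2, ApRh1, AsRh2
MspRh1	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
MpuRh1	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
AsRh3	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
AsRh4	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
OtRh1	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
OtRh2	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
OlRh1	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
OlRh2	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
OlRh3	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
OlRh4	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
DsRh1	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
GtRh2	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
GtRh3	FALSE	L	Leucine	Non-polar	Green	MspRh1, MpuRh1, AsRh3-4, OtRh1-2, OlRh1-4, DsRh1, GtRh2,3
Cop5	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
Cop6	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
Cop7	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
Vop5	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
Vop6	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
Vop7	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GpRh3	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GpRh4	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GpRh5	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GtRh4	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GtRh5	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GtRh6	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GtRh7	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GtRh8	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GtRh9	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GtRh10	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
AsRh1	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
MspRh2	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
MpuRh2	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
CsRh1	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
BgRh1	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
BgRh2	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
KnRh1	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
KnRh2	FALSE	M	Methionine	Non-polar	Green	Cop5-7, Vop5-7, GpRh3-5, GtRh4-10, AsRh1, MspRh2, MpuRh2, CsRh1, BgRh1-2, KnRh1-2
GtRh1	FALSE	D	Aspartate	Acidic	unknown	GtRh1
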