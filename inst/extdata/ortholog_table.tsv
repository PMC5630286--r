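mouse_symbol	human_symbol	mouse_mrna	human_mrna
Bai3	BAI3	NM_175642	NM_001704
Dock7	DOCK7	NM_026082	NM_033407
Gapvd1	GAPVD1	NM_025975	NM_015635
Kif14	KIF14	NM_001081258	NM_014875
Lrfn2	LRFN2	NM_027452	NM_020737
Kmt2d	KMT2D	NM_001033276	NM_003482
Kmt2c	KMT2C	NM_001081383	NM_170606
Myo3a	MYO3A	NM_148413	NM_017433
Obsl1	OBSL1	NM_178884	NM_015311
Or2k2	OR2K2	NM_146325	NM_205859
Piwil4	PIWIL4	NM_177905	NM_152431
Slco5a1	SLCO5A1	NM_172841	NM_030958
Smyd1	SMYD1	NM_009762	NM_198274
Tnxb	TNXB	NM_031176	NM_019105
Ubn2	UBN2	NM_175512	NM_173569
Wdr11	WDR11	NM_172255	NM_018117
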