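gene	mouse	lichter	parsons	pugh_cho	robinson
BAI3	WNT (1: M)	-	-	G3 (1: M)	WNT (1: M)
DOCK7	WNT (1: M)	WNT (1: M)	-	-	-
GAPVD1	WNT (1: M)	-	-	G4 (1: N)	-
KIF14	WNT (1: M)	G3 (1: M)	-	G3 (1: M)	-
LRFN2	G3 (1: M)	-	-	-	G3 (1: M)
KMT2D	WNT (1: N)	WNT (3: M2,N)	SHH,U,WNT (12: F6,M4,N2)	G3,G4,SHH (10: N5,F3,M2)	G3,SHH,U (5: F3,M,N)
KMT2C	WNT (1: M)	G3,G4 (2: M,N)	U,WNT (3: N3)	G3,G4 (4: M3,S)	U (1: N)
MYO3A	G3 (1: S)	-	-	SHH (1: M)	-
OBSL1	WNT (1: M)	-	-	SHH (1: M)	-
OR2K2	WNT (1: M)	-	-	-	SHH (1: N)
PIWIL4	G3 (1: D)	SHH (1: M)	-	-	G3 (1: M)
SLCO5A1	WNT (1: M)	-	-	G4 (1: M)	-
SMYD1	G3 (1: M)	-	-	-	WNT (1: M)
TNXB	WNT (1: M)	G3 (1: M)	-	G3 (1: M)	G3 (1: M)
UBN2	G3 (1: M)	-	-	-	SHH (1: M)
WDR11	G3 (1: M)	-	-	G3 (1: M)	-
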