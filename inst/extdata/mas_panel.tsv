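rgene	linkage_group	marker	marker_type	coupling_allele	gala_ref
Fb_E	12	ChFbE06	SSR	260	243/243
Fb_E	12	FBsnFBE-1_Y230	SNP	C	NA
Fb_E	12	FBsnFBE-2_Y495	SNP	C	NA
FB_MR5	3	FEM47	SSR	218	202/225
FB_MR5	3	FEM19	SSR	157	145/165
FB_MR5	3	FB-MR5_SNP_M106	SNP	A	NA
FB_MR5	3	FB-MR5_SNP_R209	SNP	A	NA
FB_F7	7	AE10-375	SCAR	375 (0)	NA
FB_F7	7	GE-8019	SCAR	397 (0)	NA
FB_F7	7	SNP_FB_0716011	SNP	A	NA
FB_F7	7	SNP_FB_0716013	SNP	C	NA
Rvi2	2	CH05e03	SSR	173	179/190
Rvi2	2	OPL19	SCAR	438 (0)	NA
Rvi2	2	FbsnRvi2-1_M417	SNP	A	NA
Rvi2	2	FBsnRvi2-2_M341	SNP	C	NA
Rvi2	2	FBsnRvi2-3_M58	SNP	T	NA
Rvi2	2	FBsnRvi2-4_R489	SNP	A	NA
Rvi2	2	FBsnRvi2-5_M366	SNP	A	NA
Rvi2	2	FBsnRvi2-6_1_M95	SNP	A	NA
Rvi2	2	FBsnRvi2-6_2_M133	SNP	C	NA
Rvi2	2	FBsnRvi2-7_Y292	SNP	C	NA
Rvi2	2	FBsnRvi2-8_R243	SNP	G	NA
Rvi4	2	CH02C02a	SSR	182	148/184
Rvi4	2	Hi22d06	SSR	132	132/138
Rvi4	2	FBsnRvi4.1_K146	SNP	T	NA
Rvi4	2	TNL1_Rvi4_R131	SNP	G	NA
Rvi6	1	CH-Vf1	SSR	164	146/146
Rvi6	1	M8S_Rvi6_Y124	SNP	T	NA
Rvi6	1	M18_Rvi6_Y32	SNP	T	NA
Pl1	12	AT20	SCAR	458 (0)	NA
Pl1	12	SNP_12_30034791	SNP	A	NA
Pl1	12	SNP_12_30781908	SNP	A	NA
Pl2	11	CH04H02	SSR	186	184/200
Pl2	11	FBsnPl2-1_Y245	SNP	C	NA
Pl2	11	FBsnPl2-1_R531	SNP	G	NA
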