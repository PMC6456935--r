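sample_id	gender	age	lesion	level	cluster
T_D_None_B.24	M	74	2×2 mm	SSA	B
T_D_None_B.23	F	62	2×2 mm	SSA	B
T_D_None_A.3	M	72	2×3 mm	SSA	A
T_D_None_A.25	M	65	3×2 mm	SSA	A
T_D_None_B.2	F	41	3×2 mm	SSA	B
T_D_None_B.15	F	52	3×2 mm	SSA	B
T_D_None_B.1	F	74	3×3 mm	SSA	B
T_D_None_B.27	F	72	3×3 mm	SSA	B
T_D_None_B.30	F	62	3×3 mm	SSA	B
T_D_None_A.14	M	45	4x3mm	SSA	A
T_D_None_A.26	M	28	3×4 mm	SSA	A
T_D_None_B.7	F	62	4×3 mm	SSA	B
T_D_None_B.22	M	79	4×4 mm	SSA	B
T_D_None_B.21	F	34	4×4 mm	SSA	B
T_D_None_A.28	M	59	6×3 mm	LSA	A
T_D_None_A.9	F	73	4×5 mm	LSA	A
T_D_None_A.12	F	29	6×4 mm	LSA	A
T_D_None_A.8	F	52	6×5 mm	LSA	A
T_D_None_A.19	F	61	5×6 mm	LSA	A
T_D_None_A.29	M	34	6×5 mm	LSA	A
T_D_None_A.5	M	41	8×5 mm	LSA	A
T_D_None_A.Xy	F	42	8×5 mm	LSA	A
T_D_None_A.13	M	83	6×7 mm	LSA	A
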