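name	formula	charge	phase	dGf0_kJ_mol	dHf0_kJ_mol	source
H2O	H2O1	0	liquid-water	-237.18	-285.83	Shock & Helgeson (1988) compilation
H+	H1	1	aqueous	0	0	convention (zero by definition)
SO4-2	S1O4	-2	aqueous	-744.0	-909.3	Shock & Helgeson (1988) compilation
HS-	H1S1	-1	aqueous	12.05	-16.3	Shock & Helgeson (1988) compilation
HCO3-	C1H1O3	-1	aqueous	-586.85	-689.93	Shock & Helgeson (1988) compilation
CO	C1O1	0	aqueous	-119.90	-120.96	Amend & Shock (2001) compilation
H2	H2	0	aqueous	17.72	-4.18	Amend & Shock (2001) compilation
CH4	C1H4	0	aqueous	-34.35	-87.81	Amend & Shock (2001) compilation
acetate	C2H3O2	-1	aqueous	-369.32	-486.13	Shock & Helgeson (1990) compilation
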