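# dhipea functional registry, version 1
# Columns are tab separated. family: global_hybrid | lc_hybrid | global_DH | RS_DH | LC_DH.
# alpha_x is the fraction of exact exchange (short-range value for range-separated
# functionals), c_os/c_ss the opposite-/same-spin weights of the second-order
# correction (a global alpha_C is encoded as c_os = c_ss = alpha_C), omega the
# range-separation parameter in bohr^-1 (NA when not range separated).
# n_params is the number of empirical parameters of the functional.
# adc2_supported marks functionals for which the iterative ADC(2)-based ansatz
# is defined in addition to the perturbative CIS(D)-based one.
# param_source: "defining publication" when alpha_x/c_os/c_ss/omega are taken
# from the cited reference; "representative" when they are typical values for
# the family and the defining reference should be consulted before production
# use. Class and parameter count are authoritative in either case.
name	family	exchange	correlation	alpha_x	c_os	c_ss	omega	n_params	adc2_supported	param_source	citation
SCS-RS-PBE-P86	RS_DH	PBE	P86	1.0	1.1	0.6	0.45	4	TRUE	representative	Mester & Kallay 2021
SOS-RS-PBE-P86	RS_DH	PBE	P86	1.0	1.3	0.0	0.45	3	TRUE	representative	Mester & Kallay 2021
SCS-wPBEPP86	LC_DH	PBE	P86	0.0	1.0	0.6	0.30	7	FALSE	representative	Casanova-Paez & Goerigk 2020
SOS-wPBEPP86	LC_DH	PBE	P86	0.0	1.2	0.0	0.30	5	FALSE	representative	Casanova-Paez & Goerigk 2020
DSD-PBEP86	global_DH	PBE	P86	0.70	0.53	0.25	NA	4	TRUE	defining publication	Kozuch & Martin 2011
PBE0-2	global_DH	PBE	PBE	0.793701	0.5	0.5	NA	2	TRUE	defining publication	Chai & Mao 2012
SOS-PBE0-2	global_DH	PBE	PBE	0.793701	0.6	0.0	NA	3	TRUE	representative	SOS variant of PBE0-2
PBE-QIDH	global_DH	PBE	PBE	0.693361	0.333333	0.333333	NA	2	TRUE	defining publication	Bremond et al. 2014
B2GPPLYP	global_DH	B88	LYP	0.65	0.36	0.36	NA	2	TRUE	defining publication	Karton et al. 2008
wB97X-D	lc_hybrid	B97	B97	0.222036	0	0	0.20	18	FALSE	defining publication	Chai & Head-Gordon 2008
CAM-B3LYP	lc_hybrid	B88	LYP	0.19	0	0	0.33	3	FALSE	defining publication	Yanai et al. 2004
PBE0	global_hybrid	PBE	PBE	0.25	0	0	NA	1	FALSE	defining publication	Adamo & Barone 1999
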