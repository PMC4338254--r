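individual_id	population	phenotypic_sex	band_observed
ind0001	Mexico	F	1
ind0002	Mexico	F	1
ind0003	Mexico	F	1
ind0004	Mexico	F	1
ind0005	Mexico	F	1
ind0006	Mexico	F	1
ind0007	Mexico	F	1
ind0008	Mexico	F	1
ind0009	Mexico	F	1
ind0010	Mexico	F	1
ind0011	Mexico	F	1
ind0012	Mexico	F	1
ind0013	unassigned	F	0
ind0014	Mexico	F	1
ind0015	Mexico	F	1
ind0016	Mexico	F	1
ind0017	Mexico	F	1
ind0018	Mexico	F	1
ind0019	Mexico	F	1
ind0020	Mexico	F	1
ind0021	Mexico	F	1
ind0022	Mexico	F	1
ind0023	Mexico	F	1
ind0024	Mexico	F	1
ind0025	Mexico	F	1
ind0026	Mexico	M	0
ind0027	Mexico	M	0
ind0028	Mexico	M	0
ind0029	Mexico	M	0
ind0030	Mexico	M	0
ind0031	Mexico	M	0
ind0032	Mexico	M	0
ind0033	Mexico	M	0
ind0034	Mexico	M	0
ind0035	Mexico	M	0
ind0036	Mexico	M	0
ind0037	Mexico	M	0
ind0038	Mexico	M	0
ind0039	Mexico	M	0
ind0040	Mexico	M	0
ind0041	Mexico	M	0
ind0042	Mexico	M	0
ind0043	Mexico	M	0
ind0044	Mexico	M	0
ind0045	NewZealand	F	1
ind0046	NewZealand	F	1
ind0047	NewZealand	F	1
ind0048	NewZealand	F	1
ind0049	NewZealand	F	1
ind0050	NewZealand	F	1
ind0051	NewZealand	F	1
ind0052	NewZealand	F	1
ind0053	NewZealand	F	1
ind0054	NewZealand	F	1
ind0055	NewZealand	F	1
ind0056	NewZealand	F	1
ind0057	NewZealand	F	1
ind0058	NewZealand	F	1
ind0059	NewZealand	F	1
ind0060	NewZealand	F	1
ind0061	NewZealand	F	1
ind0062	NewZealand	F	1
ind0063	NewZealand	F	1
ind0064	NewZealand	F	1
ind0065	NewZealand	F	1
ind0066	NewZealand	F	1
ind0067	NewZealand	F	1
ind0068	NewZealand	F	1
ind0069	NewZealand	F	1
ind0070	NewZealand	F	1
ind0071	NewZealand	F	1
ind0072	NewZealand	F	1
ind0073	NewZealand	F	1
ind0074	NewZealand	M	0
ind0075	NewZealand	M	0
ind0076	NewZealand	M	0
ind0077	NewZealand	M	0
ind0078	NewZealand	M	0
ind0079	NewZealand	M	0
ind0080	NewZealand	M	0
ind0081	NewZealand	M	0
ind0082	NewZealand	M	0
ind0083	NewZealand	M	0
ind0084	NewZealand	M	0
ind0085	NewZealand	M	0
ind0086	NewZealand	M	0
ind0087	NewZealand	M	0
ind0088	NewZealand	M	0
ind0089	NewZealand	M	0
ind0090	NewZealand	M	0
ind0091	NewZealand	M	0
ind0092	NewZealand	M	0
ind0093	NewZealand	M	0
ind0094	NewZealand	M	0
ind0095	NewZealand	M	0
ind0096	NewZealand	M	0
ind0097	NewZealand	M	0
ind0098	NewZealand	M	0
ind0099	NewZealand	M	0
ind0100	NewZealand	M	0
ind0101	NewZealand	M	0
ind0102	NewZealand	M	0
ind0103	NewZealand	M	0
ind0104	NewZealand	M	0
ind0105	NewZealand	M	0
ind0106	NewZealand	M	0
ind0107	NewZealand	M	0
ind0108	NewZealand	M	0
ind0109	NewZealand	M	0
ind0110	NewZealand	M	0
ind0111	NewZealand	M	0
ind0112	NewZealand	M	0
ind0113	NewZealand	M	0
ind0114	NewZealand	M	0
ind0115	NewZealand	M	0
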