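A1	synthetic placeholder signature (no biological meaning)	SYN0001	SYN0002	SYN0003	SYN0004	SYN0005	SYN0006	SYN0007	SYN0008	SYN0009	SYN0010	SYN0011	SYN0012	SYN0013	SYN0014	SYN0015	SYN0016	SYN0017	SYN0018	SYN0019	SYN0020	SYN0021	SYN0022	SYN0023	SYN0024	SYN0025	SYN0026	SYN0027	SYN0028	SYN0029	SYN0030	SYN0031	SYN0032	SYN0033	SYN0034	SYN0035	SYN0036	SYN0037	SYN0038	SYN0039	SYN0040	SYN0041	SYN0042	SYN0043	SYN0044	SYN0045	SYN0046	SYN0047	SYN0048	SYN0049	SYN0050
A2	synthetic placeholder signature (no biological meaning)	SYN0051	SYN0052	SYN0053	SYN0054	SYN0055	SYN0056	SYN0057	SYN0058	SYN0059	SYN0060	SYN0061	SYN0062	SYN0063	SYN0064	SYN0065	SYN0066	SYN0067	SYN0068	SYN0069	SYN0070	SYN0071	SYN0072	SYN0073	SYN0074	SYN0075	SYN0076	SYN0077	SYN0078	SYN0079	SYN0080	SYN0081	SYN0082	SYN0083	SYN0084	SYN0085	SYN0086	SYN0087	SYN0088	SYN0089	SYN0090	SYN0091	SYN0092	SYN0093	SYN0094	SYN0095	SYN0096	SYN0097	SYN0098	SYN0099	SYN0100
fetal	synthetic placeholder signature (no biological meaning)	SYN0101	SYN0102	SYN0103	SYN0104	SYN0105	SYN0106	SYN0107	SYN0108	SYN0109	SYN0110	SYN0111	SYN0112	SYN0113	SYN0114	SYN0115	SYN0116	SYN0117	SYN0118	SYN0119	SYN0120	SYN0121	SYN0122	SYN0123	SYN0124	SYN0125	SYN0126	SYN0127	SYN0128	SYN0129	SYN0130	SYN0131	SYN0132	SYN0133	SYN0134	SYN0135	SYN0136	SYN0137	SYN0138	SYN0139	SYN0140	SYN0141	SYN0142	SYN0143	SYN0144	SYN0145	SYN0146	SYN0147	SYN0148	SYN0149	SYN0150
adult	synthetic placeholder signature (no biological meaning)	SYN0151	SYN0152	SYN0153	SYN0154	SYN0155	SYN0156	SYN0157	SYN0158	SYN0159	SYN0160	SYN0161	SYN0162	SYN0163	SYN0164	SYN0165	SYN0166	SYN0167	SYN0168	SYN0169	SYN0170	SYN0171	SYN0172	SYN0173	SYN0174	SYN0175	SYN0176	SYN0177	SYN0178	SYN0179	SYN0180	SYN0181	SYN0182	SYN0183	SYN0184	SYN0185	SYN0186	SYN0187	SYN0188	SYN0189	SYN0190	SYN0191	SYN0192	SYN0193	SYN0194	SYN0195	SYN0196	SYN0197	SYN0198	SYN0199	SYN0200
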