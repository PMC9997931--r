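gene001	GO:0000001
gene002	GO:0000001
gene003	GO:0000001
gene004	GO:0000001
gene005	GO:0000001
gene006	GO:0000001
gene007	GO:0000001
gene008	GO:0000001
gene009	GO:0000001
gene010	GO:0000001
gene011	GO:0000001
gene012	GO:0000001
gene013	GO:0000001
gene014	GO:0000001
gene015	GO:0000001
gene016	GO:0000001
gene017	GO:0000001
gene018	GO:0000001
gene019	GO:0000001
gene020	GO:0000001
gene021	GO:0000001
gene022	GO:0000001
gene023	GO:0000001
gene024	GO:0000001
gene025	GO:0000001
gene026	GO:0000001
gene027	GO:0000001
gene028	GO:0000001
gene029	GO:0000001
gene030	GO:0000001
gene031	GO:0000001
gene032	GO:0000001
gene033	GO:0000001
gene034	GO:0000001
gene035	GO:0000001
gene036	GO:0000001
gene037	GO:0000001
gene038	GO:0000001
gene039	GO:0000001
gene040	GO:0000001
gene041	GO:0000001
gene042	GO:0000001
gene043	GO:0000001
gene044	GO:0000001
gene045	GO:0000001
gene046	GO:0000001
gene047	GO:0000001
gene048	GO:0000001
gene049	GO:0000001
gene050	GO:0000001
gene051	GO:0000001
gene052	GO:0000001
gene053	GO:0000001
gene054	GO:0000001
gene055	GO:0000001
gene056	GO:0000001
gene057	GO:0000001
gene058	GO:0000001
gene059	GO:0000001
gene060	GO:0000001
gene061	GO:0000001
gene062	GO:0000001
gene063	GO:0000001
gene064	GO:0000001
gene065	GO:0000001
gene066	GO:0000001
gene067	GO:0000001
gene068	GO:0000001
gene069	GO:0000001
gene070	GO:0000001
gene071	GO:0000001
gene072	GO:0000001
gene073	GO:0000001
gene074	GO:0000001
gene075	GO:0000001
gene076	GO:0000001
gene077	GO:0000001
gene078	GO:0000001
gene079	GO:0000001
gene080	GO:0000001
gene081	GO:0000001
gene082	GO:0000001
gene083	GO:0000001
gene084	GO:0000001
gene085	GO:0000001
gene086	GO:0000001
gene087	GO:0000001
gene088	GO:0000001
gene089	GO:0000001
gene090	GO:0000001
gene091	GO:0000001
gene092	GO:0000001
gene093	GO:0000001
gene094	GO:0000001
gene095	GO:0000001
gene096	GO:0000001
gene097	GO:0000001
gene098	GO:0000001
gene099	GO:0000001
gene100	GO:0000001
gene101	GO:0000001
gene102	GO:0000001
gene103	GO:0000001
gene104	GO:0000001
gene105	GO:0000001
gene106	GO:0000001
gene107	GO:0000001
gene108	GO:0000001
gene109	GO:0000001
gene110	GO:0000001
gene111	GO:0000001
gene112	GO:0000001
gene113	GO:0000001
gene114	GO:0000001
gene115	GO:0000001
gene116	GO:0000001
gene117	GO:0000001
gene118	GO:0000001
gene119	GO:0000001
gene120	GO:0000001
gene121	GO:0000001
gene122	GO:0000001
gene123	GO:0000001
gene124	GO:0000001
gene125	GO:0000001
gene126	GO:0000001
gene127	GO:0000001
gene128	GO:0000001
gene129	GO:0000001
gene130	GO:0000001
gene131	GO:0000001
gene132	GO:0000001
gene133	GO:0000001
gene134	GO:0000001
gene135	GO:0000001
gene136	GO:0000001
gene137	GO:0000001
gene138	GO:0000001
gene139	GO:0000001
gene140	GO:0000001
gene141	GO:0000001
gene142	GO:0000001
gene143	GO:0000001
gene144	GO:0000001
gene145	GO:0000001
gene146	GO:0000001
gene147	GO:0000001
gene148	GO:0000001
gene149	GO:0000001
gene150	GO:0000001
gene151	GO:0000001
gene152	GO:0000001
gene153	GO:0000001
gene154	GO:0000001
gene155	GO:0000001
gene156	GO:0000001
gene157	GO:0000001
gene158	GO:0000001
gene159	GO:0000001
gene160	GO:0000001
gene161	GO:0000001
gene162	GO:0000001
gene163	GO:0000001
gene164	GO:0000001
gene165	GO:0000001
gene166	GO:0000001
gene167	GO:0000001
gene168	GO:0000001
gene169	GO:0000001
gene170	GO:0000001
gene171	GO:0000001
gene172	GO:0000001
gene173	GO:0000001
gene174	GO:0000001
gene175	GO:0000001
gene176	GO:0000001
gene177	GO:0000001
gene178	GO:0000001
gene179	GO:0000001
gene180	GO:0000001
gene181	GO:0000001
gene182	GO:0000001
gene183	GO:0000001
gene184	GO:0000001
gene185	GO:0000001
gene186	GO:0000001
gene187	GO:0000001
gene188	GO:0000001
gene189	GO:0000001
gene190	GO:0000001
gene191	GO:0000001
gene192	GO:0000001
gene193	GO:0000001
gene194	GO:0000001
gene195	GO:0000001
gene196	GO:0000001
gene197	GO:0000001
gene198	GO:0000001
gene199	GO:0000001
gene200	GO:0000001
gene001	GO:0000011
gene002	GO:0000011
gene003	GO:0000011
gene004	GO:0000011
gene005	GO:0000011
gene006	GO:0000011
gene007	GO:0000011
gene008	GO:0000011
gene009	GO:0000011
gene010	GO:0000011
gene011	GO:0000011
gene012	GO:0000011
gene010	GO:0000012
gene011	GO:0000012
gene012	GO:0000012
gene013	GO:0000012
gene014	GO:0000012
gene015	GO:0000012
gene016	GO:0000012
gene017	GO:0000012
gene018	GO:0000012
gene019	GO:0000012
gene020	GO:0000012
gene021	GO:0000012
gene022	GO:0000012
gene023	GO:0000012
gene024	GO:0000012
gene030	GO:0000021
gene031	GO:0000021
gene032	GO:0000021
gene033	GO:0000021
gene034	GO:0000021
gene035	GO:0000021
gene036	GO:0000021
gene037	GO:0000021
gene038	GO:0000021
gene039	GO:0000021
gene040	GO:0000021
gene041	GO:0000021
gene042	GO:0000021
gene043	GO:0000021
gene044	GO:0000021
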