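probe_id	gene	chrom	start	end	kind	value
CN_TUBGCP5_01	TUBGCP5	chr15	22833595	22833654	copy_number	0
CN_TUBGCP5_02	TUBGCP5	chr15	22873631	22873690	copy_number	0
CN_CYFIP1_01	CYFIP1	chr15	22892848	22892907	copy_number	0
CN_CYFIP1_02	CYFIP1	chr15	23003415	23003474	copy_number	0
CN_NIPA2_01	NIPA2	chr15	23004884	23004943	copy_number	0
CN_NIPA2_02	NIPA2	chr15	23034167	23034226	copy_number	0
CN_NIPA1_01	NIPA1	chr15	23043480	23043539	copy_number	0
CN_NIPA1_02	NIPA1	chr15	23086387	23086446	copy_number	0
CN_MKRN3_01	MKRN3	chr15	23810654	23810713	copy_number	0
CN_MKRN3_02	MKRN3	chr15	23812906	23812965	copy_number	0
CN_MAGEL2_01	MAGEL2	chr15	23888895	23888954	copy_number	0
CN_MAGEL2_02	MAGEL2	chr15	23892733	23892792	copy_number	0
CN_NDN_01	NDN	chr15	23930754	23930813	copy_number	0
CN_NDN_02	NDN	chr15	23932190	23932249	copy_number	0
CN_NPAP1_01	NPAP1	chr15	24920741	24920800	copy_number	0
CN_SNRPN_01	SNRPN	chr15	25200331	25200390	copy_number	0
CN_SNRPN_02	SNRPN	chr15	25204959	25205018	copy_number	0
CN_SNRPN_03	SNRPN	chr15	25209586	25209645	copy_number	0
CN_SNRPN_04	SNRPN	chr15	25214214	25214273	copy_number	0
CN_SNRPN_05	SNRPN	chr15	25218841	25218900	copy_number	0
CN_SNRPN_06	SNRPN	chr15	25223469	25223528	copy_number	0
CN_UBE3A_01	UBE3A	chr15	25582596	25582655	copy_number	0
CN_UBE3A_02	UBE3A	chr15	25607914	25607973	copy_number	0
CN_UBE3A_03	UBE3A	chr15	25633232	25633291	copy_number	0
CN_UBE3A_04	UBE3A	chr15	25658550	25658609	copy_number	0
CN_UBE3A_05	UBE3A	chr15	25683868	25683927	copy_number	0
CN_ATP10A_01	ATP10A	chr15	25924060	25924119	copy_number	0
CN_ATP10A_02	ATP10A	chr15	26108089	26108148	copy_number	0
CN_GABRA5_01	GABRA5	chr15	27112066	27112125	copy_number	0
CN_GABRA5_02	GABRA5	chr15	27194097	27194156	copy_number	0
CN_GABRG3_01	GABRG3	chr15	27216629	27216688	copy_number	0
CN_OCA2_01	OCA2	chr15	28000221	28000280	copy_number	0
CN_OCA2_02	OCA2	chr15	28344201	28344260	copy_number	0
CN_HERC2_01	HERC2	chr15	28356386	28356445	copy_number	0
CN_HERC2_02	HERC2	chr15	28567038	28567097	copy_number	0
CN_APBA2_01	APBA2	chr15	29213924	29213983	copy_number	0
REF_01	REF01	chr2	3.1e+07	31000059	copy_number	0
REF_02	REF02	chr3	3.2e+07	32000059	copy_number	0
REF_03	REF03	chr5	3.3e+07	33000059	copy_number	0
REF_04	REF04	chr7	3.4e+07	34000059	copy_number	0
REF_05	REF05	chr9	3.5e+07	35000059	copy_number	0
REF_06	REF06	chr11	3.6e+07	36000059	copy_number	0
REF_07	REF07	chr12	3.7e+07	37000059	copy_number	0
REF_08	REF08	chr16	3.8e+07	38000059	copy_number	0
REF_09	REF09	chr17	3.9e+07	39000059	copy_number	0
REF_10	REF10	chr19	4e+07	40000059	copy_number	0
REF_11	REF11	chr20	4.1e+07	41000059	copy_number	0
ME_SNRPN_01	SNRPN	chr15	25200300	25200359	methylation	0
ME_SNRPN_02	SNRPN	chr15	25205000	25205059	methylation	0
ME_SNRPN_03	SNRPN	chr15	25210000	25210059	methylation	0
ME_MAGEL2_01	MAGEL2	chr15	23888900	23888959	methylation	0
ME_MAGEL2_02	MAGEL2	chr15	23890500	23890559	methylation	0
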