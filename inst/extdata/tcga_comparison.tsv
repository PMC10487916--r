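feature_id	fc_study	p_study	fdr_study	fc_tcga	p_tcga	fdr_tcga
hsa-let-7a-5p	-8.81174	5.50e-07	5.29e-06	-1.03695	0.004	0.06594
hsa-let-7b-5p	-5.27658	1.00e-07	1.40e-06	-1.15425	0.010	0.10343
hsa-let-7f-5p	-4.62780	2.86e-07	3.26e-06	-1.05391	0.006	0.07720
hsa-let-7g-5p	-4.45426	2.27e-06	1.59e-05	-0.57203	0.032	0.17183
hsa-miR-10a-5p	-2.32238	5.63e-09	1.40e-07	-1.60710	0.005	0.07131
hsa-miR-10b-5p	-1.86443	4.05e-06	2.55e-05	-0.93191	0.022	0.16072
hsa-miR-146b-3p	0.40531	6.10e-04	0.001503	1.46182	0.002	0.03960
hsa-miR-181c-5p	-1.87328	8.15e-05	3.24e-04	-0.82176	0.045	0.21220
hsa-miR-191-5p	-6.27011	4.31e-08	7.16e-07	-1.33551	0.000	0.01904
hsa-miR-195-5p	-2.90058	4.43e-07	4.53e-06	-1.10876	0.044	0.20910
hsa-miR-200a-3p	-2.42572	1.90e-04	6.41e-04	-1.31242	0.011	0.11347
hsa-miR-200b-3p	-5.03990	2.95e-06	1.93e-05	-1.07680	0.016	0.14109
hsa-miR-26a-5p	-4.78689	2.76e-07	3.24e-06	-0.70270	0.042	0.20410
hsa-miR-26b-5p	-4.82779	1.57e-07	2.03e-06	-0.95776	0.017	0.14177
hsa-miR-29b-3p	-5.32329	5.97e-07	5.68e-06	-0.95562	0.031	0.16993
hsa-miR-29c-3p	-4.26978	2.44e-08	4.64e-07	-1.67903	0.000	0.01904
hsa-miR-30a-5p	-3.51938	1.90e-05	9.15e-05	-1.90155	5.71e-05	0.00646
hsa-miR-30b-5p	-4.62253	8.25e-08	1.24e-06	-0.89401	0.003	0.05813
hsa-miR-342-3p	-4.73665	8.75e-09	2.05e-07	-1.49716	0.005	0.06655
hsa-miR-34a-5p	-2.44624	3.34e-07	3.65e-06	-0.72461	0.025	0.16814
hsa-miR-423-5p	-2.72085	7.42e-06	4.14e-05	-0.84124	0.021	0.16072
hsa-miR-664a-3p	-1.71081	1.43e-04	5.20e-04	-0.87318	0.021	0.16072
hsa-miR-766-3p	2.89894	1.71e-09	5.93e-08	1.20479	0.000	0.02093
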