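feature_id	log2_fc	p_value	fdr	cytoband	cna
hsa-miR-661	4.12434	1.75e-13	1.75e-11	8q24.3	gain
hsa-miR-765	3.65976	4.88e-15	9.75e-13	1q23.1	gain
hsa-miR-3151-5p	2.63406	7.04e-07	6.46e-06	8q22.3	gain
hsa-miR-2053	2.94650	1.75e-08	3.49e-07	8q23.3	gain
hsa-miR-548d-5p	1.98169	6.27e-06	3.58e-05	8q24.13	gain
hsa-miR-6721-5p	1.58740	4.62e-04	0.00129	6p21.32	gain
hsa-miR-548d-3p	1.50149	2.90e-05	1.32e-04	8q24.13	gain
hsa-miR-638	1.17150	1.68e-04	5.82e-04	19p13.2	gain
hsa-miR-1224-5p	0.99921	3.44e-04	0.00103	3q27.1	gain
hsa-miR-3150b-3p	0.49202	2.65e-04	8.55e-04	8q22.1	gain
hsa-miR-1204	0.40531	6.10e-04	0.00150	8q24.21	gain
hsa-miR-4448	0.39551	7.85e-04	0.00179	3q27.1	gain
hsa-miR-218-5p	-2.71112	5.71e-08	9.12e-07	5q34	loss
hsa-miR-146a-5p	-2.81117	1.85e-06	1.35e-05	5q33.3	loss
hsa-miR-145-5p	-4.69634	8.57e-08	1.24e-06	5q32	loss
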