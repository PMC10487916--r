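chrom	cytoband	start	stop	size_printed	n_cases	pct	direction	n_probes	consistent
chr1	q21.1-q24.2	144374546	168000000	23435182	6	28.5	gain	533	FALSE
chr3	q26.1-q27.2	166346288	185000000	18991985	5	23.8	gain	132	FALSE
chr4	p16.3-p15.31	1914109	20323997	18409889	4	19.01	loss	243	TRUE
chr5	q21.1-q35.3	99381621	172000000	72831986	4	19.01	loss	1048	FALSE
chr6	p25.3-p24.2	248239	10815671	10567433	8	33.33	loss	16	TRUE
chr6	p22.3-p21.32	17745590	32262768	14517179	4	19.01	gain	321	TRUE
chr8	q13-q24.3	69999338	146000000	75139299	7	33.33	gain	1038	FALSE
chr8	q24.3	141355101	145000000	3898583	7	33.33	gain	587	FALSE
chr11	q13.2-q13.3	68249411	70012823	1763413	4	19.01	gain	31	TRUE
chr19	p13.3-p13.11	781586	17833369	17051784	7	33.33	gain	560	TRUE
chr21	q21.3-q22.3	28834275	45382723	16549449	4	19.01	gain	344	FALSE
chrX	p22.33	1179089	2353577	1174489	7	33.33	loss	42	TRUE
chrX	p22.33	218292	2622294	2404303	5	23.8	gain	75	FALSE
chrX	p22.33-p22.2	2662039	13621701	10959663	10	47.6	loss	149	TRUE
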