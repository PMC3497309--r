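# Group means and standard deviations of seven growth/morphology traits for
# diploid and colchicine-induced autotetraploid birch (Betula platyphylla)
# from four full-sib families, measured in a common-garden field trial.
# Units: height m; breast_height_diameter mm; volume dm3; leaf_area cm2;
# fruit_length mm; fruit_diameter mm; stoma_length um.
family	ploidy	trait	mean	sd
5x3	diploid	height	6.80	0.25
5x3	autotetraploid	height	5.61	0.49
5x9	diploid	height	6.86	0.17
5x9	autotetraploid	height	5.70	0.43
5x11	diploid	height	6.83	0.22
5x11	autotetraploid	height	5.52	0.48
6x5	diploid	height	6.92	0.18
6x5	autotetraploid	height	5.48	0.37
5x3	diploid	breast_height_diameter	36.44	1.13
5x3	autotetraploid	breast_height_diameter	46.71	3.00
5x9	diploid	breast_height_diameter	36.59	0.91
5x9	autotetraploid	breast_height_diameter	47.30	3.02
5x11	diploid	breast_height_diameter	37.88	1.80
5x11	autotetraploid	breast_height_diameter	46.05	3.35
6x5	diploid	breast_height_diameter	37.59	0.83
6x5	autotetraploid	breast_height_diameter	45.70	3.12
5x3	diploid	volume	4.09	0.29
5x3	autotetraploid	volume	5.96	1.07
5x9	diploid	volume	4.15	0.24
5x9	autotetraploid	volume	6.17	1.02
5x11	diploid	volume	4.45	0.52
5x11	autotetraploid	volume	5.74	1.02
6x5	diploid	volume	4.41	0.25
6x5	autotetraploid	volume	5.61	0.91
5x3	diploid	leaf_area	13.92	5.62
5x3	autotetraploid	leaf_area	28.81	8.63
5x9	diploid	leaf_area	20.77	4.82
5x9	autotetraploid	leaf_area	26.44	5.57
5x11	diploid	leaf_area	13.51	3.87
5x11	autotetraploid	leaf_area	30.64	8.90
6x5	diploid	leaf_area	14.48	3.97
6x5	autotetraploid	leaf_area	27.83	6.40
5x3	diploid	fruit_length	40.70	2.53
5x3	autotetraploid	fruit_length	48.17	5.25
5x9	diploid	fruit_length	44.51	5.22
5x9	autotetraploid	fruit_length	50.87	6.06
5x11	diploid	fruit_length	45.62	3.59
5x11	autotetraploid	fruit_length	48.53	5.07
6x5	diploid	fruit_length	51.78	6.07
6x5	autotetraploid	fruit_length	57.63	8.39
5x3	diploid	fruit_diameter	8.55	0.58
5x3	autotetraploid	fruit_diameter	11.43	2.88
5x9	diploid	fruit_diameter	8.02	0.53
5x9	autotetraploid	fruit_diameter	12.76	2.04
5x11	diploid	fruit_diameter	9.11	0.59
5x11	autotetraploid	fruit_diameter	12.03	1.19
6x5	diploid	fruit_diameter	9.02	0.77
6x5	autotetraploid	fruit_diameter	11.31	1.46
5x3	diploid	stoma_length	11.09	1.33
5x3	autotetraploid	stoma_length	23.19	5.06
5x9	diploid	stoma_length	16.73	2.04
5x9	autotetraploid	stoma_length	26.31	4.17
5x11	diploid	stoma_length	11.78	1.60
5x11	autotetraploid	stoma_length	27.28	4.64
6x5	diploid	stoma_length	11.84	1.34
6x5	autotetraploid	stoma_length	20.81	3.43
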