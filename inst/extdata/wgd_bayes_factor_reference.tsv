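# Reference set of WGD hypothesis tests: posterior mean retention rates and
# Savage-Dickey Bayes factors for eight WGD hypotheses under the relaxed and
# critical branch-specific DL+WGD models, with their published evidence
# classifications (strong / substantial / barely against H0, or H0 supported).
hypothesis	model	q_mean	K	verdict
WGD1	relaxed	0.001	1272.297	supports H0
WGD1	critical	0.029	2.693	supports H0
WGD2	relaxed	0.028	2.649	supports H0
WGD2	critical	0.058	0.393	barely against H0
WGD3	relaxed	0.352	0.047	strong against H0
WGD3	critical	0.263	0.061	strong against H0
WGD4	relaxed	0.170	0.197	substantial against H0
WGD4	critical	0.193	0.094	strong against H0
WGD5	relaxed	0.156	0.149	substantial against H0
WGD5	critical	0.006	128.480	supports H0
WGD6	relaxed	0.020	21.026	supports H0
WGD6	critical	0.000	6919.539	supports H0
WGD7	relaxed	0.127	0.166	substantial against H0
WGD7	critical	0.142	0.135	substantial against H0
WGD8	relaxed	0.025	12.864	supports H0
WGD8	critical	0.027	6.007	supports H0
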