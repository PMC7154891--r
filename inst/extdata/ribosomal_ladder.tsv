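dataset	model	minus_lnL	printed_deviance	printed_df	printed_p
mtLSU	homogeneous	22486.50	NA	NA	NA
mtLSU	M1	22438.91	95.18	17	6.88e-13
mtLSU	M2	22436.54	4.73	1	0.0296
mtLSU	terminal_clades	22425.82	21.43	3	8.56e-05
mtLSU	per_branch	22327.36	196.92	176	0.1337
mtSSU	homogeneous	14603.13	NA	NA	NA
mtSSU	M1	14556.56	93.14	15	2.57e-13
mtSSU	M2	14556.50	0.12	1	0.7234
mtSSU	terminal_clades	14548.21	16.58	3	0.0009
mtSSU	per_branch	14415.88	264.66	178	2.66e-05
nSSU	homogeneous	14023.18	NA	NA	NA
nSSU	M1	13984.94	76.47	19	7.47e-09
nSSU	M2	13970.40	29.08	1	6.94e-08
nSSU	terminal_clades	13967.78	5.23	3	0.1555
nSSU	per_branch	13878.57	178.42	174	0.3933
cpLSU	homogeneous	23520.96	NA	NA	NA
cpLSU	M1	23324.90	392.13	19	0
cpLSU	M2	23323.04	3.71	1	0.0540
cpLSU	terminal_clades	23287.39	71.31	3	2.22e-15
cpLSU	per_branch	23083.32	408.13	174	0
cpSSU	homogeneous	9895.45	NA	NA	NA
cpSSU	M1	9816.46	157.97	19	0
cpSSU	M2	9816.37	0.17	1	0.6795
cpSSU	terminal_clades	9808.42	15.90	3	0.0012
cpSSU	per_branch	9695.43	225.98	174	0.0049
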