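trait	slope_GBLUP	slope_BayesA	slope_BayesB	slope_BayesCpi	slope_BayesR	mse_GBLUP	mse_BayesA	mse_BayesB	mse_BayesCpi	mse_BayesR
ADG	0.63	0.67	0.70	0.93	0.96	0.16	0.17	0.17	0.16	0.15
LW	0.84	0.85	0.83	1.08	1.04	45.48	47.16	46.21	46.51	46.54
CW	0.72	0.74	0.76	0.94	0.95	27.26	29.99	29.79	28.73	28.94
DP	0.87	0.88	0.91	0.65	0.88	2.34	2.40	2.41	2.54	2.48
LMP	0.28	0.31	0.27	0.47	0.43	2.44	2.49	2.47	2.42	2.46
ST	1.56	1.58	1.59	1.76	1.79	19.00	19.41	19.44	22.08	20.12
SR	0.82	0.82	0.86	0.85	0.88	1.42	1.45	1.45	1.45	1.45
CR	0.59	0.61	0.62	0.70	0.76	1.55	1.55	1.55	1.55	1.56
TD	1.01	1.04	1.09	1.19	1.21	2.36	2.42	2.37	2.36	2.35
FS	0.94	0.95	0.97	0.98	0.99	0.49	0.49	0.53	0.49	0.48
BI	0.96	1.00	1.07	1.27	1.25	0.88	0.88	0.89	0.88	0.87
OU	0.83	0.84	0.87	0.92	0.94	0.18	0.20	0.19	0.19	0.18
ER	0.78	0.77	0.78	0.81	0.87	1.65	1.84	1.92	1.91	1.89
KN	0.67	0.67	0.77	0.78	0.79	1.65	1.64	2.12	1.75	1.96
ICO	0.70	0.72	0.74	0.90	0.85	1.10	1.11	1.45	1.12	1.35
HS	0.75	0.76	0.86	0.87	0.89	1.41	1.41	1.55	1.40	1.48
RMW	0.94	0.95	0.97	1.15	1.02	0.86	0.87	0.84	0.92	0.89
BFT	0.45	0.37	0.45	0.50	0.48	0.96	0.96	0.96	0.96	0.97
pH	1.98	1.95	2.08	1.33	1.32	1.71	1.71	1.75	1.72	1.74
SF	1.39	0.64	0.63	0.79	0.76	1.30	1.30	1.31	1.31	1.31
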