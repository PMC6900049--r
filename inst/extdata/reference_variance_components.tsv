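trait	sigma_a2	sigma_e2	h2	se_h2
ADG	0.012	0.013	0.47	0.03
LW	663.380	1139.880	0.37	0.02
CW	299.650	361.820	0.45	0.02
DP	0.950	4.960	0.16	0.02
LMP	0.850	5.110	0.14	0.01
ST	0.380	1.160	0.24	0.02
SR	0.490	1.390	0.26	0.01
CR	1.080	2.880	0.27	0.02
TD	0.078	0.120	0.39	0.03
FS	0.150	0.220	0.40	0.02
CM	0.008	0.009	0.47	0.02
OU	1.320	0.880	0.60	0.04
ER	1.200	1.130	0.52	0.03
KN	0.590	0.360	0.62	0.04
ICO	0.910	0.880	0.51	0.03
HS	0.370	0.230	0.61	0.02
RMW	126.130	169.570	0.43	0.02
BFT	0.330	2.940	0.10	0.01
pH	0.005	0.112	0.04	0.01
SF	0.340	2.000	0.15	0.01
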