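trait	ability_GBLUP	ability_BayesA	ability_BayesB	ability_BayesCpi	ability_BayesR	accuracy_GBLUP	accuracy_BayesA	accuracy_BayesB	accuracy_BayesCpi	accuracy_BayesR
ADG	0.194	0.197	0.197	0.204	0.214	0.283	0.287	0.288	0.298	0.312
LW	0.231	0.232	0.230	0.239	0.242	0.379	0.381	0.378	0.393	0.398
CW	0.251	0.253	0.252	0.261	0.268	0.374	0.377	0.376	0.389	0.400
DP	0.111	0.111	0.112	0.109	0.119	0.277	0.276	0.279	0.273	0.298
LMP	0.061	0.061	0.061	0.059	0.069	0.162	0.164	0.162	0.159	0.184
ST	0.239	0.238	0.241	0.239	0.254	0.487	0.486	0.492	0.487	0.518
SR	0.178	0.179	0.176	0.177	0.184	0.349	0.352	0.345	0.348	0.361
CR	0.168	0.169	0.169	0.169	0.176	0.322	0.326	0.324	0.325	0.339
TD	0.277	0.278	0.278	0.283	0.291	0.444	0.446	0.446	0.453	0.466
FS	0.249	0.250	0.254	0.250	0.252	0.394	0.395	0.402	0.395	0.398
CM	0.240	0.240	0.250	0.247	0.251	0.350	0.351	0.365	0.360	0.366
OU	0.346	0.347	0.347	0.352	0.358	0.447	0.448	0.447	0.455	0.462
ER	0.354	0.353	0.355	0.358	0.361	0.491	0.490	0.492	0.497	0.501
KN	0.315	0.304	0.339	0.312	0.311	0.400	0.385	0.431	0.396	0.395
ICO	0.258	0.259	0.259	0.269	0.268	0.362	0.363	0.363	0.377	0.375
HS	0.325	0.326	0.376	0.332	0.331	0.416	0.417	0.481	0.425	0.424
RMW	0.267	0.268	0.262	0.271	0.278	0.408	0.409	0.399	0.414	0.424
BFT	0.074	0.072	0.074	0.076	0.077	0.235	0.227	0.233	0.241	0.243
pH	0.073	0.073	0.073	0.074	0.078	0.366	0.365	0.365	0.370	0.390
SF	0.109	0.107	0.107	0.114	0.119	0.280	0.277	0.277	0.294	0.307
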