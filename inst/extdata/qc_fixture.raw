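FID IID PAT MAT SEX PHENOTYPE snpA_A snpB_A snpC_A snpD_A snpE_A snpF_A
cow01 cow01 0 0 0 -9 2 2 1 0 0 1
cow02 cow02 0 0 0 -9 0 1 0 0 2 1
cow03 cow03 0 0 0 -9 1 1 0 0 1 1
cow04 cow04 0 0 0 -9 0 1 0 2 1 1
cow05 cow05 0 0 0 -9 2 0 0 0 1 1
cow06 cow06 0 0 0 -9 1 2 0 2 1 1
cow07 cow07 0 0 0 -9 1 0 0 2 1 1
cow08 cow08 0 0 0 -9 0 0 0 2 1 2
cow09 cow09 0 0 0 -9 0 1 0 2 0 2
cow10 cow10 0 0 0 -9 2 1 0 2 1 0
cow11 cow11 0 0 0 -9 0 2 0 2 1 0
cow12 cow12 0 0 0 -9 1 2 0 2 0 0
cow13 cow13 0 0 0 -9 1 NA 0 2 0 1
cow14 cow14 0 0 0 -9 1 2 0 0 1 1
cow15 cow15 0 0 0 -9 2 0 0 0 0 2
cow16 cow16 0 0 0 -9 1 0 0 0 2 1
cow17 cow17 0 0 0 -9 0 0 0 0 0 2
cow18 cow18 0 0 0 -9 0 0 0 2 1 1
cow19 cow19 0 0 0 -9 2 1 0 0 0 2
cow20 cow20 0 0 0 -9 1 0 0 0 1 1
cow21 cow21 0 0 0 -9 1 0 0 0 1 0
cow22 cow22 0 0 0 -9 1 0 0 2 0 1
cow23 cow23 0 0 0 -9 0 1 0 0 1 2
cow24 cow24 0 0 0 -9 0 0 0 0 0 0
cow25 cow25 0 0 0 -9 2 1 0 0 0 1
cow26 cow26 0 0 0 -9 2 0 0 2 0 1
cow27 cow27 0 0 0 -9 2 1 0 2 0 0
cow28 cow28 0 0 0 -9 2 1 0 0 0 1
cow29 cow29 0 0 0 -9 1 0 0 2 0 1
cow30 cow30 0 0 0 -9 1 2 0 2 0 1
cow31 cow31 0 0 0 -9 0 NA 0 2 1 0
cow32 cow32 0 0 0 -9 1 1 0 2 0 0
cow33 cow33 0 0 0 -9 1 1 0 0 0 2
cow34 cow34 0 0 0 -9 1 1 0 2 0 0
cow35 cow35 0 0 0 -9 1 0 0 0 0 0
cow36 cow36 0 0 0 -9 1 1 0 2 1 1
cow37 cow37 0 0 0 -9 1 1 0 2 1 0
cow38 cow38 0 0 0 -9 2 1 0 0 2 1
cow39 cow39 0 0 0 -9 1 1 0 0 0 2
cow40 cow40 0 0 0 -9 1 1 0 0 2 0
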