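compound	formula	mz_mh_published	smiles
30901	C27H23N3O5	470.1712	N#CC1=C(N)OC2=C(C(=O)Oc3ccccc32)C12C(=O)N1C(C)(C)CC(C)c3cc(OC)cc2c31
225738	C28H28N2O4	457.2123	COC(=O)c1c(C)[nH]c(-c2ccccc2)c1C1C(=O)N2C(C)(C)C=C(C)c3cc(OC)cc1c23
38292	C28H26N4O3	467.2079	N#CC1=C(N)OC2=C(C(=O)Nc3ccccc32)C12C(=O)N1C(C)(C)CC(C)c3cc(CC)cc2c31
38756	C21H17N3O4	376.1293	N#CC1=C(N)OC2=C(C(=O)Nc3ccccc32)C1c1ccc(OC)c(OC)c1
41453	C28H31N3O	426.2541	O=C1N2C3(CCCCC3)CC(C)(C)c3cccc(c23)C15NCCc2c5[nH]c3ccccc23
224530	C18H18N2O	279.1493	Nc1c2CC(C)CCc2nc2oc(-c3ccccc3)cc12
224533	C17H13ClN2O2	313.0739	Nc1c2C(=O)CCCc2nc2oc(-c3ccccc3Cl)cc12
225635	C16H19N5O2	314.1612	NC(=N)NN=C1C(=O)N2C(C)(C)C=C(C)c3cc(OC)cc1c23
225638	C26H30FN7O2	492.2519	NC(=N)NN=C1C(=O)N2C(C)(C)C=C(CN3CCN(c4ccc(F)cc4)CC3)c3cc(OC)cc1c23
225746	C22H20N2O4	377.1497	O=C(ON=C1C(=O)N2C(C)(C)C=C(C)c3cc(OC)cc1c23)c1ccccc1
225006	C24H28N4O4	437.2185	CC1CC(C)(C)N(C)c2cc3oc(=O)c(-c4cc(=O)[nH]c(N5CCOCC5)n4)cc3cc12
224870	C24H25NO4	392.1858	CC1CC(C)(C)N(C)c2cc3oc(=O)c(C(=O)c4ccc(OC)cc4)cc3cc12
225624	C26H26FN3O4	464.1981	O=C1C(=O)N2C(C)(C)C=C(CN3CCN(Cc4ccc5OCOc5c4)CC3)c3cc(F)cc1c23
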