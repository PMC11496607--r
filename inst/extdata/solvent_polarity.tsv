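name	smiles	et30	sp	sdp	sa	sb	aliases	citation
toluene	Cc1ccccc1	33.9	0.782	0.284	0.000	0.128	methylbenzene	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
THF	C1CCOC1	37.4	0.714	0.634	0.000	0.591	tetrahydrofuran	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
MeOH	CO	55.4	0.608	0.904	0.605	0.545	methanol	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
MeCN	CC#N	45.6	0.645	0.974	0.044	0.286	acetonitrile	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
hexane	CCCCCC	31.0	0.616	0.000	0.000	0.056	n-hexane	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
H2O	O	63.1	0.681	0.997	1.062	0.025	water	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
EtOH	CCO	51.9	0.633	0.783	0.400	0.658	ethanol	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
ethyl acetate	CCOC(C)=O	38.1	0.656	0.603	0.000	0.542	EtOAc	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
DMSO	CS(C)=O	45.1	0.830	1.000	0.072	0.647	dimethyl sulfoxide	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
DMF	CN(C)C=O	43.2	0.759	0.977	0.031	0.613	dimethylformamide,N,N-dimethylformamide	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
CHCl3	ClC(Cl)Cl	39.1	0.783	0.614	0.047	0.071	chloroform	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
CH2Cl2	ClCCl	40.7	0.761	0.769	0.040	0.178	dichloromethane,DCM	Reichardt Chem. Rev. 1994; Catalan J. Phys. Chem. B 2009
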