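id,smiles,tt,note
3a,CCOC(=O)c1c[nH]c2nc(C(=O)OCC)nn2c1=O,359,"2,6-diethoxycarbonyl-1,2,4-triazolo[1,5-a]pyrimidin-7-one; TT = 30 s x 1.9 x 6.3"
3f,CCOC(=O)c1c[nH]c2nc(-c3cccs3)nn2c1=O,60,2-(thien-2-yl)-6-ethoxycarbonyl analog; fold reconstructed
3g,O=c1n2nc(-c3cccnc3)nc2[nH]cc1[N+](=O)[O-],90,2-(pyridin-3-yl)-6-nitro; drawn neutral; fold reconstructed
3h,O=c1n2nc(-c3ccccc3)nc2[n-]cc1[N+](=O)[O-].c1cc[nH+]cc1,105,pyridinium salt of 2-phenyl-6-nitro anion; fold reconstructed
3i,O=c1n2nc(-c3ccco3)nc2[n-]cc1[N+](=O)[O-].c1cc[nH+]cc1,150,pyridinium salt of 2-(fur-2-yl)-6-nitro anion; fold reconstructed
3j,O=c1n2nc(-c3cccs3)nc2[n-]cc1[N+](=O)[O-].c1cc[nH+]cc1,120,pyridinium salt of 2-(thien-2-yl)-6-nitro anion; fold reconstructed
3k,O=c1n2nc(-c3ccc(o3)[N+](=O)[O-])nc2[n-]cc1[N+](=O)[O-].c1cc[nH+]cc1,302,pyridinium salt of 2-(5-nitrofur-2-yl)-6-nitro anion; TT = 30 s x 1.6 x 6.3
3l,O=c1n2nc(-c3ccccc3)c(C#N)c2[n-]cc1[N+](=O)[O-].c1cc[nH+]cc1,75,pyridinium salt of 2-phenyl-3-cyano-6-nitropyrazolo analog; fold reconstructed
3m,O=c1n2nc(-c3ccc(o3)[N+](=O)[O-])nc2[nH]c(C)c1[N+](=O)[O-],359,2-(5-nitrofur-2-yl)-5-methyl-6-nitro; TT = 30 s x 1.9 x 6.3
3n,O=c1n2nc(-c3ccco3)nc2[n-]cc1[N+](=O)[O-].[Na+],397,sodium salt of 2-(fur-2-yl)-6-nitro anion; TT = 30 s x 2.1 x 6.3
3o,O=c1n2nc(-c3ccco3)nc2[n-]cc1[N+](=O)[O-].[NH4+],150,ammonium salt; fold reconstructed
3p,O=c1n2nc(-c3ccco3)nc2[n-]cc1[N+](=O)[O-].C1COCC[NH2+]1,135,morpholinium salt; fold reconstructed
3q,O=c1n2nc(-c3ccco3)nc2[n-]cc1[N+](=O)[O-].NC(CCCNC(N)=[NH2+])C(O)=O,165,L-argininium salt; fold reconstructed
6a,O=c1c2ncn(CCc3ccc(O)cc3)c2nc2scnn12,90,3-(4-hydroxyphenylethyl)thiadiazolopurinone; fold reconstructed
6b,O=c1c2ncn(C3CC3)c2nc2scnn12,75,3-cyclopropyl analog; fold reconstructed
6c,O=c1c2ncn(CCCCOC(OCC)OCC)c2nc2scnn12,189,diethoxymethyloxybutyl analog; TT = 30 s x 6.3 (comparable to reference)
9,O=c1n2c3ccccc3[n-]c2ncc1[N+](=O)[O-].[Na+],60,sodium salt of 3-nitrobenzimidazopyrimidinone; fold reconstructed
13a,Cc1ccc(cc1)n1nc2c(-c3ccc(OC)c(OC)c3OC)nc3nc4ccccc4n3c2n1,45,trimethoxyphenyl tetracycle; fold reconstructed
13b,Cc1ccc(cc1)n1nc2c(-c3ccc(OC)c(OC)c3)nc3nc4ccccc4n3c2n1,48,dimethoxyphenyl tetracycle; fold reconstructed
13c,Cc1ccc(cc1)n1nc2c(-c3cccs3)nc3nc4ccccc4n3c2n1,42,thienyl tetracycle; fold reconstructed
13d,Cc1ccc(cc1)n1nc2c(-c3cccn3C)nc3nc4ccccc4n3c2n1,45,N-methylpyrrolyl tetracycle; fold reconstructed
13e,Cc1ccc(cc1)n1nc2c(-c3c(O)ccc4ccccc34)nc3nc4ccccc4n3c2n1,51,naphthol tetracycle; fold reconstructed
14a,Cc1ccc(cc1)n1nc2c(-c3ccc(OC)c(OC)c3OC)nc3nc4cc(F)c(F)cc4n3c2n1,48,difluoro trimethoxyphenyl tetracycle; fold reconstructed
dabigatran,Cn1c2ccc(C(=O)N(CCC(O)=O)c3ccccn3)cc2nc1CNc1ccc(C(=N)N)cc1,NA,reference drug (active form); not in training set
dabigatran_etexilate,CCCCCCOC(=O)N=C(N)c1ccc(NCc2nc3cc(C(=O)N(CCC(=O)OCC)c4ccccn4)ccc3n2C)cc1,189,reference drug (prodrug as dosed); TT = 30 s x 6.3
apixaban,COc1ccc(cc1)n1nc(C(N)=O)c2CCN(c3ccc(cc3)N3CCCCC3=O)C(=O)c12,36,reference drug; TT = 30 s x 1.2
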