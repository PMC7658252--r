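rule_id,smarts,demerit,description
D001,[NX2]=[NX2+]=[NX1-],100,azide
D002,"[CX3](=[OX1])[F,Cl,Br,I]",100,acyl halide
D003,[NX2]=[CX2]=[OX1],100,isocyanate
D004,[CX3H1]=[OX1],40,aldehyde
D005,[CX4]1[OX2][CX4]1,100,epoxide
D006,[CX4]1[NX3][CX4]1,100,aziridine
D007,[CX3]=[CX3][CX3]=[OX1],50,Michael acceptor
D008,"[CX4;H1,H2][Br,I]",60,reactive alkyl halide
D009,[NX3;!$([NX3][CX3]=[OX1])][NX3;!$([NX3][CX3]=[OX1])],50,hydrazine
D010,[NX3+](=[OX1])[O-],25,nitro group
D011,[SX2H],60,free thiol
D012,[NX4+],25,quaternary nitrogen
D013,[OX2H1]c1ccccc1[OX2H1],50,catechol
D014,[CX3](=[OX1])[OX2][CX3](=[OX1]),100,anhydride
D015,[SX4](=[OX1])(=[OX1])Cl,100,sulfonyl chloride
D016,[NX2]=[OX1],75,nitroso
D017,[OX2][OX2],100,peroxide
D018,[CX3]=[NX2][#6],25,imine
D019,[BX3]([OX2H1])[OX2H1],30,boronic acid
D020,[CX2]#[CX2H1],30,terminal alkyne
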