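# tRNA isoacceptor copy numbers in six red algal plastid genomes,
# transcribed from published annotations. Anticodon strings are kept
# exactly as printed in the source (3'-5' direction).
species	trnA(GGC)	trnA(TGC)	trnC(GCA)	trnD(GTC)	trnE(TTC)	trnF(GAA)	trnG(GCC)	trnG(TCC)	trnH(GTG)	trnI(GAT)	trnK(TTT)	trnL(CAA)	trnL(GAG)	trnL(TAA)	trnL(TAG)	trnM(CAT)	trnN(GTT)	trnP(TGG)	trnQ(TTG)	trnR(ACG)	trnR(CCG)	trnR(CCT)	trnR(TCT)	trnS(CGA)	trnS(GCT)	trnS(GGA)	trnS(TGA)	trnT(GGT)	trnT(TGT)	trnV(GAC)	trnV(TAC)	trnW(CCA)	trnY(GTA)
C_caldarium	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	3	1	1	1	1	1	0	1	0	1	0	1	1	1	1	1	1	1
C_merolae	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	3	1	1	1	1	0	0	1	0	1	1	1	1	1	1	1	1	1
P_purpurea	1	2	1	1	1	1	1	1	1	2	1	1	1	1	1	3	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
P_yezoensis	1	2	1	1	1	1	1	1	1	2	1	1	1	1	2	3	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
G_tenuistipitata	0	1	1	1	1	1	1	1	1	1	1	1	0	1	1	2	1	1	1	1	1	0	1	0	1	0	1	1	1	1	1	1	1
G_taiwanensis	0	1	1	1	1	1	1	1	1	1	1	1	0	1	1	2	1	1	1	1	1	0	1	0	1	0	1	1	1	1	1	1	1
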