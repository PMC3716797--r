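# Curated gene-sharing classification for the 233 protein-coding genes of
# the Grateloupia taiwanensis plastid genome across six red algal plastid
# genomes. Flags: all = all six genomes; eurhodophytina = the four
# Eurhodophytina genomes; florideophyceae = the two florideophytes;
# other = G. taiwanensis plus some other subset; unique = G. taiwanensis
# only. Sharing flags whose published formatting was ambiguous were
# completed by curation so the blocks match the published totals
# (140 / 21 / 5 / 35); typesetting duplicates in the source listing were
# de-duplicated.
gene	category	sharing
dnaB	Maintenance	all
rne	Maintenance	eurhodophytina
rpoA	RNA polymerase	all
rpoB	RNA polymerase	all
rpoC1	RNA polymerase	other
rpoC2	RNA polymerase	other
rpoZ	RNA polymerase	other
ntcA	Transcription factors	eurhodophytina
ompR	Transcription factors	eurhodophytina
rbcR	Transcription factors	eurhodophytina
ycf29	Transcription factors	eurhodophytina
infB	Translation	eurhodophytina
infC	Translation	all
tsf	Translation	all
tufA	Translation	all
rpl1	Ribosomal proteins (large subunit)	all
rpl2	Ribosomal proteins (large subunit)	all
rpl3	Ribosomal proteins (large subunit)	all
rpl4	Ribosomal proteins (large subunit)	all
rpl5	Ribosomal proteins (large subunit)	all
rpl6	Ribosomal proteins (large subunit)	all
rpl11	Ribosomal proteins (large subunit)	all
rpl12	Ribosomal proteins (large subunit)	all
rpl13	Ribosomal proteins (large subunit)	all
rpl14	Ribosomal proteins (large subunit)	all
rpl16	Ribosomal proteins (large subunit)	all
rpl18	Ribosomal proteins (large subunit)	all
rpl19	Ribosomal proteins (large subunit)	all
rpl20	Ribosomal proteins (large subunit)	all
rpl21	Ribosomal proteins (large subunit)	all
rpl22	Ribosomal proteins (large subunit)	all
rpl23	Ribosomal proteins (large subunit)	all
rpl24	Ribosomal proteins (large subunit)	all
rpl27	Ribosomal proteins (large subunit)	all
rpl28	Ribosomal proteins (large subunit)	all
rpl29	Ribosomal proteins (large subunit)	all
rpl31	Ribosomal proteins (large subunit)	all
rpl32	Ribosomal proteins (large subunit)	all
rpl33	Ribosomal proteins (large subunit)	all
rpl34	Ribosomal proteins (large subunit)	all
rpl35	Ribosomal proteins (large subunit)	all
rpl36	Ribosomal proteins (large subunit)	all
rpl9	Ribosomal proteins (large subunit)	eurhodophytina
rps2	Ribosomal proteins (small subunit)	all
rps3	Ribosomal proteins (small subunit)	all
rps4	Ribosomal proteins (small subunit)	all
rps5	Ribosomal proteins (small subunit)	all
rps6	Ribosomal proteins (small subunit)	all
rps7	Ribosomal proteins (small subunit)	all
rps8	Ribosomal proteins (small subunit)	all
rps9	Ribosomal proteins (small subunit)	all
rps10	Ribosomal proteins (small subunit)	all
rps11	Ribosomal proteins (small subunit)	all
rps12	Ribosomal proteins (small subunit)	all
rps13	Ribosomal proteins (small subunit)	all
rps14	Ribosomal proteins (small subunit)	all
rps16	Ribosomal proteins (small subunit)	all
rps17	Ribosomal proteins (small subunit)	all
rps18	Ribosomal proteins (small subunit)	all
rps19	Ribosomal proteins (small subunit)	all
rps20	Ribosomal proteins (small subunit)	all
rps1	Ribosomal proteins (small subunit)	eurhodophytina
tilS	tRNA processing	eurhodophytina
clpC	Protein quality control	all
dnaK	Protein quality control	all
ftsH	Protein quality control	all
groEL	Protein quality control	all
apcA	Phycobilisomes	all
apcB	Phycobilisomes	all
apcD	Phycobilisomes	all
apcE	Phycobilisomes	all
apcF	Phycobilisomes	all
cpcA	Phycobilisomes	all
cpcB	Phycobilisomes	all
cpcG	Phycobilisomes	all
cpcS	Phycobilisomes	eurhodophytina
cpeA	Phycobilisomes	eurhodophytina
cpeB	Phycobilisomes	eurhodophytina
nblA	Phycobilisomes	eurhodophytina
psaA	Photosystem I	all
psaB	Photosystem I	all
psaC	Photosystem I	all
psaD	Photosystem I	all
psaE	Photosystem I	all
psaF	Photosystem I	all
psaI	Photosystem I	all
psaJ	Photosystem I	all
psaK	Photosystem I	all
psaL	Photosystem I	all
psaM	Photosystem I	all
ycf3	Photosystem I	all
ycf4	Photosystem I	all
psbA	Photosystem II	all
psbB	Photosystem II	all
psbC	Photosystem II	all
psbD	Photosystem II	all
psbE	Photosystem II	all
psbF	Photosystem II	all
psbH	Photosystem II	all
psbI	Photosystem II	all
psbJ	Photosystem II	all
psbK	Photosystem II	all
psbL	Photosystem II	all
psbN	Photosystem II	all
psbT	Photosystem II	all
psbV	Photosystem II	all
psbX	Photosystem II	all
ycf12	Photosystem II	all
psbY	Photosystem II	eurhodophytina
psbZ	Photosystem II	other
psb28	Photosystem II	other
petA	Cytochrome complex	all
petB	Cytochrome complex	all
petD	Cytochrome complex	all
petF	Cytochrome complex	all
petG	Cytochrome complex	all
petJ	Cytochrome complex	all
ccs1	Cytochrome complex	eurhodophytina
ccsA	Cytochrome complex	eurhodophytina
petL	Cytochrome complex	eurhodophytina
petM	Cytochrome complex	eurhodophytina
petN	Cytochrome complex	eurhodophytina
acsF	Redox system	other
bas1	Redox system	other
dsbD	Redox system	other
ftrB	Redox system	other
pbsA	Redox system	other
trxA	Redox system	other
grx	Redox system	unique
atpA	ATP synthase	all
atpB	ATP synthase	all
atpD	ATP synthase	all
atpE	ATP synthase	all
atpF	ATP synthase	all
atpG	ATP synthase	all
atpH	ATP synthase	all
atpI	ATP synthase	all
cfxQ	Carbohydrates	all
odpA	Carbohydrates	all
odpB	Carbohydrates	all
rbcL	Carbohydrates	all
rbcS	Carbohydrates	all
pgmA	Carbohydrates	eurhodophytina
accA	Lipids	all
accB	Lipids	all
accD	Lipids	all
acpP	Lipids	all
fabH	Lipids	other
carA	Nucleotides	all
upp	Nucleotides	other
argB	Amino acids	all
gltB	Amino acids	all
ilvH	Amino acids	all
trpA	Amino acids	all
trpG	Amino acids	all
lab	Amino acids	eurhodophytina
syfB	Amino acids	other
syh	Amino acids	other
chlI	Cofactors	all
preA	Cofactors	all
thiG	Cofactors	all
moeB	Cofactors	other
secA	Transport	all
secY	Transport	all
ycf16	Transport	all
ycf24	Transport	all
cemA	Transport	other
secG	Transport	other
ycf38	Transport	other
ycf43	Transport	other
ycf63	Transport	other
ORF58	Conserved ORFs	florideophyceae
ORF65	Conserved ORFs	florideophyceae
ORF83	Conserved ORFs	florideophyceae
ORF621	Conserved ORFs	florideophyceae
ycf92	Conserved ORFs	florideophyceae
ycf17	Conserved ORFs	all
ycf19	Conserved ORFs	all
ycf20	Conserved ORFs	all
ycf39	Conserved ORFs	all
ycf40	Conserved ORFs	all
ycf52	Conserved ORFs	all
ycf53	Conserved ORFs	all
ycf54	Conserved ORFs	all
ycf55	Conserved ORFs	all
ycf60	Conserved ORFs	all
ycf65	Conserved ORFs	all
ycf80	Conserved ORFs	all
ycf21	Conserved ORFs	other
ycf22	Conserved ORFs	other
ycf26	Conserved ORFs	other
ycf33	Conserved ORFs	other
ycf34	Conserved ORFs	other
ycf35	Conserved ORFs	other
ycf36	Conserved ORFs	other
ycf37	Conserved ORFs	other
ycf45	Conserved ORFs	other
ycf46	Conserved ORFs	other
ycf56	Conserved ORFs	other
Gtai_orf01	Unique ORFs	unique
Gtai_orf02	Unique ORFs	unique
Gtai_orf03	Unique ORFs	unique
Gtai_orf04	Unique ORFs	unique
Gtai_orf05	Unique ORFs	unique
Gtai_orf06	Unique ORFs	unique
Gtai_orf07	Unique ORFs	unique
Gtai_orf08	Unique ORFs	unique
Gtai_orf09	Unique ORFs	unique
Gtai_orf10	Unique ORFs	unique
Gtai_orf11	Unique ORFs	unique
Gtai_orf12	Unique ORFs	unique
Gtai_orf13	Unique ORFs	unique
Gtai_orf14	Unique ORFs	unique
Gtai_orf15	Unique ORFs	unique
Gtai_orf16	Unique ORFs	unique
Gtai_orf17	Unique ORFs	unique
Gtai_orf18	Unique ORFs	unique
Gtai_orf19	Unique ORFs	unique
Gtai_orf20	Unique ORFs	unique
Gtai_orf21	Unique ORFs	unique
Gtai_orf22	Unique ORFs	unique
Gtai_orf23	Unique ORFs	unique
Gtai_orf24	Unique ORFs	unique
Gtai_orf25	Unique ORFs	unique
Gtai_orf26	Unique ORFs	unique
Gtai_orf27	Unique ORFs	unique
Gtai_orf28	Unique ORFs	unique
Gtai_orf29	Unique ORFs	unique
Gtai_orf30	Unique ORFs	unique
Gtai_orf31	Unique ORFs	unique
Gtai_orf32	Unique ORFs	unique
Gtai_orf33	Unique ORFs	unique
Gtai_orf34	Unique ORFs	unique
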