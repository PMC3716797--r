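accA
accB
accD
acpP
acsF
apcA
apcB
apcC
apcD
apcE
apcF
argB
atpA
atpB
atpD
atpE
atpF
atpG
atpH
atpI
bas1
carA
ccs1
ccsA
cemA
cfxQ
chlB
chlI
chlL
chlN
clpC
cpcA
cpcB
cpcC
cpcD
cpcG
cpcS
cpeA
cpeB
cpeS
cysA
cysT
dnaB
dnaK
dsbD
fabH
ftrB
ftsH
glnB
gltA
gltB
groEL
grx
hemA
ilvB
ilvH
infB
infC
lab
menA
menB
menC
menD
menE
minD
minE
moeB
nblA
nblB
ntcA
odpA
odpB
ompR
ORF58
ORF621
ORF65
ORF83
pbsA
petA
petB
petD
petF
petG
petJ
petL
petM
petN
pgmA
preA
psaA
psaB
psaC
psaD
psaE
psaF
psaI
psaJ
psaK
psaL
psaM
psb28
psbA
psbB
psbC
psbD
psbE
psbF
psbH
psbI
psbJ
psbK
psbL
psbN
psbT
psbV
psbW
psbX
psbY
psbZ
rbcL
rbcR
rbcS
rne
rpl1
rpl11
rpl12
rpl13
rpl14
rpl16
rpl18
rpl19
rpl2
rpl20
rpl21
rpl22
rpl23
rpl24
rpl27
rpl28
rpl29
rpl3
rpl31
rpl32
rpl33
rpl34
rpl35
rpl36
rpl4
rpl5
rpl6
rpl9
rpoA
rpoB
rpoC1
rpoC2
rpoZ
rps1
rps10
rps11
rps12
rps13
rps14
rps16
rps17
rps18
rps19
rps2
rps20
rps3
rps4
rps5
rps6
rps7
rps8
rps9
secA
secD
secF
secG
secY
syfB
syh
tatC
thiG
thiS
tilS
trpA
trpE
trpG
trxA
tsf
tufA
tyrA
upp
ycf12
ycf16
ycf17
ycf19
ycf20
ycf21
ycf22
ycf24
ycf26
ycf29
ycf3
ycf33
ycf34
ycf35
ycf36
ycf37
ycf38
ycf39
ycf4
ycf40
ycf43
ycf45
ycf46
ycf52
ycf53
ycf54
ycf55
ycf56
ycf60
ycf63
ycf65
ycf80
ycf92
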