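# Curated plastid gene symbol aliases (alias -> canonical).
alias	canonical
sufB	ycf24
sufC	ycf16
cbbX	cfxQ
pdhA	odpA
pdhB	odpB
psb30	ycf12
ycf30	rbcR
tuf	tufA
groL	groEL
hisS	syh
pheT	syfB
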