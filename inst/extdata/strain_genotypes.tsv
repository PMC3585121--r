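genome	gene	status	copies
Ata	idtM	functional	1
Ata	idtS	functional	1
Ata	idtG	pseudogene	1
Ata	idtB	functional	1
Ata	idtC	functional	1
Ata	idtF	functional	1
Ata	idtP	functional	1
Ata	idtQ	functional	1
Cfu	lpsC	pseudogene	1
Cfu	easA	functional	1
Cfu	lpsB	pseudogene	1
Cfu	cloA	functional	1
Cfu	easC	functional	1
Cfu	easD	functional	1
Cfu	easE	functional	1
Cfu	easF	functional	1
Cfu	easG	functional	1
Cfu	dmaW	functional	1
Cfu	easH	functional	1
Cpa	easP	functional	1
Cpa	lpsC	functional	1
Cpa	easA	functional	1
Cpa	lpsB	functional	1
Cpa	cloA	functional	1
Cpa	easC	functional	1
Cpa	easD	functional	1
Cpa	easE	pseudogene	1
Cpa	easF	functional	1
Cpa	easG	functional	1
Cpa	dmaW	functional	1
Cpa	easO	functional	1
Cpa	idtM	functional	1
Cpa	idtS	functional	1
Cpa	idtG	functional	1
Cpa	idtB	functional	1
Cpa	idtC	functional	1
Cpa	idtF	functional	1
Cpa	idtP	functional	1
Cpa	idtQ	functional	1
Cpu	easA	functional	1
Cpu	lpsB	functional	1
Cpu	cloA	functional	1
Cpu	easC	functional	1
Cpu	easD	functional	1
Cpu	easE	functional	1
Cpu	easF	functional	1
Cpu	easG	functional	1
Cpu	dmaW	functional	1
Cpu	easH	functional	1
Cpu	lpsA	functional	2
Cpu	lpsC	functional	1
Cpu	idtM	functional	1
Cpu	idtS	functional	1
Cpu	idtB	functional	1
Cpu	idtC	functional	1
Cpu	idtP	functional	1
Cpu	idtQ	functional	1
Eam	lpsA	pseudogene	1
Eam	lolF	functional	1
Eam	lolC	functional	1
Eam	lolD	functional	1
Eam	lolO	functional	1
Eam	lolA	functional	1
Eam	lolU	functional	1
Eam	lolP	pseudogene	1
Eam	lolT	functional	1
Eam	lolE	functional	1
Eam	perA	functional	1
Ebe	easC	functional	1
Ebe	easD	pseudogene	1
Ebe	easE	functional	1
Ebe	easF	functional	1
Ebe	easG	pseudogene	1
Ebe	dmaW	functional	1
Ebe	lpsA	pseudogene	1
Ebe	lolF	functional	1
Ebe	lolC	functional	1
Ebe	lolD	functional	1
Ebe	lolO	pseudogene	1
Ebe	lolA	functional	1
Ebe	lolU	functional	1
Ebe	lolT	functional	1
Ebe	lolE	functional	1
Ebe	lolM	pseudogene	1
Ebe	perA	functional	1
Eel	easC	functional	1
Eel	easE	functional	1
Eel	easF	functional	1
Eel	easG	pseudogene	1
Eel	dmaW	functional	1
Eel	perA	functional	1
Ef1	easA	functional	1
Ef1	lpsB	functional	1
Ef1	cloA	functional	1
Ef1	easC	functional	1
Ef1	easD	functional	1
Ef1	easE	functional	1
Ef1	easF	functional	1
Ef1	easG	functional	1
Ef1	dmaW	functional	1
Ef1	easH	functional	1
Ef1	lpsA	functional	1
Ef1	idtK	functional	1
Ef1	idtM	functional	1
Ef1	idtS	functional	1
Ef1	idtG	functional	1
Ef1	idtB	functional	1
Ef1	idtC	functional	1
Ef1	idtF	functional	1
Ef1	idtP	functional	1
Ef1	idtQ	functional	1
Ef1	idtE	functional	1
Ef1	idtJ	functional	1
Ef1	perA	functional	1
Ef2	easA	functional	1
Ef2	lpsB	functional	1
Ef2	cloA	functional	1
Ef2	easC	functional	1
Ef2	easD	functional	1
Ef2	easE	functional	1
Ef2	easF	functional	1
Ef2	easG	functional	1
Ef2	dmaW	functional	1
Ef2	easH	functional	1
Ef2	lpsA	functional	1
Ef2	idtB	functional	1
Ef2	idtC	functional	1
Ef2	idtF	functional	1
Ef2	idtP	functional	1
Ef2	idtQ	functional	1
Ef2	lolF	functional	1
Ef2	lolC	functional	1
Ef2	lolD	functional	1
Ef2	lolO	functional	1
Ef2	lolA	functional	1
Ef2	lolU	functional	1
Ef2	lolP	functional	1
Ef2	lolT	functional	1
Ef2	lolE	functional	1
Ef2	lolN	functional	1
Ef2	lolM	functional	1
Ef2	perA	delta_r	1
Egl	easA	functional	1
Egl	lpsB	functional	1
Egl	cloA	functional	1
Egl	easC	functional	1
Egl	easD	functional	1
Egl	easE	functional	1
Egl	easF	functional	1
Egl	easG	functional	1
Egl	dmaW	functional	1
Egl	easH	functional	1
Egl	lpsA	functional	1
Egl	lolF	functional	1
Egl	lolC	functional	1
Egl	lolD	functional	1
Egl	lolO	functional	1
Egl	lolA	functional	1
Egl	lolU	functional	1
Egl	lolT	functional	1
Egl	lolE	functional	1
Egl	lolN	pseudogene	1
Et5	easA	functional	1
Et5	lpsB	functional	1
Et5	cloA	functional	1
Et5	easC	functional	1
Et5	easD	functional	1
Et5	easE	functional	1
Et5	easF	functional	1
Et5	easG	functional	1
Et5	dmaW	functional	1
Et5	easH	functional	1
Et5	lpsA	functional	1
Et5	perA	delta_r	1
Et8	perA	functional	1
Nga	idtK	pseudogene	1
Nga	idtM	functional	1
Nga	idtS	functional	1
Nga	idtG	functional	1
Nga	idtB	functional	1
Nga	idtC	functional	1
Nga	idtF	functional	1
Nga	idtP	functional	1
Nga	idtQ	functional	1
Nga	lolD	pseudogene	1
Nga	lolO	pseudogene	1
Nga	lolA	functional	1
Nga	lolU	pseudogene	1
Ngi	easP	functional	1
Ngi	lpsC	functional	1
Ngi	easA	functional	1
Ngi	lpsB	functional	1
Ngi	cloA	functional	1
Ngi	easC	functional	1
Ngi	easD	functional	1
Ngi	easE	functional	1
Ngi	easF	functional	1
Ngi	easG	functional	1
Ngi	dmaW	functional	1
Ngi	easO	functional	1
Nun	lolF	functional	2
Nun	lolC	functional	2
Nun	lolD	functional	2
Nun	lolO	functional	2
Nun	lolA	functional	2
Nun	lolU	functional	2
Nun	lolP	functional	1
Nun	lolT	functional	2
Nun	lolE	functional	2
Nun	lolN	functional	1
Nun	lolM	functional	1
Pip	easP	functional	1
Pip	lpsC	functional	1
Pip	easA	functional	1
Pip	lpsB	functional	1
Pip	cloA	functional	1
Pip	easC	functional	1
Pip	easD	functional	1
Pip	easE	functional	1
Pip	easF	functional	1
Pip	easG	functional	1
Pip	dmaW	functional	1
Pip	easO	functional	1
Pip	easH	functional	1
Pip	lpsA	functional	1
Pip	idtK	functional	1
Pip	idtM	functional	1
Pip	idtS	functional	1
Pip	idtG	functional	1
Pip	idtB	functional	1
Pip	idtC	functional	1
Pip	idtF	functional	1
Pip	idtP	functional	1
Pip	idtQ	functional	1
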