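genome	pathway	observed_product	relation	expected_discordant	note
Eel	EAS	CC	frontier	FALSE	chanoclavine-I accumulation; only the first four pathway genes are functional
Ebe	EAS	CC	frontier	FALSE	same first-four-gene genotype as Eel
Ngi	EAS	LAH	frontier	FALSE	EN and LAH producible; lacks only lpsA and easH so no ergopeptine
Ngi	EAS	EN	producible	FALSE	ergonovine producible alongside LAH
Ngi	EAS	ergopeptine	not_producible	FALSE	blocked at lpsA and easH
Ef1	EAS	ergopeptine	frontier	FALSE	ergovaline (an ergopeptine); lacks lpsC so no EN or LAH
Ef1	EAS	EN	not_producible	FALSE	blocked at lpsC
Pip	EAS	ergopeptine	producible	FALSE	only strain with all 14 EAS genes functional
Pip	EAS	LAH	producible	FALSE	EN, LAH and an ergopeptine (ergobalansine) all producible
Cpu	EAS	ergopeptine	producible	FALSE	ergotamine and ergocryptine; two lpsA copies
Cpu	EAS	EN	producible	FALSE	EN predicted from gene content (not assayed)
Cfu	EAS	EC	producible	FALSE	elymoclavine producer; pathway terminates early through loss of functional lpsB
Cpa	EAS	none	none	FALSE	defective easE; no ergot alkaloid production predicted
Ef2	EAS	none	expected_discordant	TRUE	near-complete EAS gene set but the cluster is not expressed; no ergot alkaloids detected
Ebe	LOL	AcAP	frontier	FALSE	inactive lolO (internal deletion); accumulates 1-acetamidopyrrolizidine
Eam	LOL	NANL	frontier	FALSE	lolP pseudogene and missing lolN/lolM; accumulates NANL
Egl	LOL	NANL	frontier	FALSE	lolN pseudogene; accumulates NANL
Ef2	LOL	NFL	frontier	FALSE	full LOL gene set; N-formylloline end product
Nun	LOL	NFL	frontier	FALSE	full LOL gene set (two cluster copies); NFL end product
Ef1	IDT	LTM	frontier	FALSE	lolitrem B producer; carries idt/ltmE and idt/ltmJ
Nga	IDT	PAX	frontier	FALSE	idtK pseudogene; paxilline end product
Pip	IDT	TDK	frontier	FALSE	terpendole end product
Ef1	PER	PER	frontier	FALSE	peramine producer
Eam	PER	PER	frontier	FALSE	peramine producer
Eel	PER	PER	frontier	FALSE	peramine producer
Et8	PER	PER	frontier	FALSE	peramine producer
Ef2	PER	none	none	FALSE	perA lacking the terminal reductase domain; no peramine
Et5	PER	none	none	FALSE	perA lacking the terminal reductase domain; no peramine
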