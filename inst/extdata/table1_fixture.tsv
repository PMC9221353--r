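# Dual-day screen hits: compounds with co-culture fold-change >= 1.3 over
# in-plate DMSO controls on both screening days, with printed aggregate
# fold-changes, drug class, follow-up candidate flag, and whether the
# printed fold-change derives from a single screening day.
rank	compound_id	name	fold_change	drug_class	candidate	single_replicate
1	colistin_sulfate_salt	Colistin sulfate salt	2.02	antibiotic	TRUE	TRUE
2	nicotinamide	Nicotinamide	1.85	vitamin B3	TRUE	FALSE
3	monensin_sodium_salt	Monensin sodium salt	1.62	antibiotic	TRUE	FALSE
4	butirosin_disulfate_salt	Butirosin disulfate salt	1.60	aminoglycoside antibiotic	FALSE	FALSE
5	zafirlukast	Zafirlukast	1.54	anti-asthmatic	TRUE	FALSE
6	amphotericin_b	Amphotericin B	1.50	antifungal	FALSE	FALSE
7	argatroban	Argatroban	1.46	anti-coagulant	FALSE	FALSE
8	dimethisoquin_hydrochloride	Dimethisoquin hydrochloride	1.45	anesthetic	FALSE	FALSE
9	tizanidine_hydrochloride	Tizanidine hydrochloride	1.42	adrenergic agonist	TRUE	FALSE
10	closantel	Closantel	1.41	anti-parasitic	TRUE	FALSE
11	benazepril_hydrochloride	Benazepril hydrochloride	1.40	ACE inhibitor	TRUE	FALSE
12	diflorasone_diacetate	Diflorasone diacetate	1.40	topical steroid	TRUE	FALSE
13	butoconazole_nitrate	Butoconazole nitrate	1.38	anti-fungal	FALSE	FALSE
14	etretinate	Etretinate	1.34	retinoid	FALSE	FALSE
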