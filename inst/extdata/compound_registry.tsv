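id	series	r1_c6	r5_c8	aryl	formula	n_stereocenters	yield_pct	state	esi_mh_mz
5a	5	H	H	phenyl	C23H25N3O2	2	74	yellow oil	376
5b	5	H	H	4-OMe	C24H27N3O3	2	64	yellow oil	406
5c	5	H	H	3,4-diOMe	C25H29N3O4	2	65	yellow oil	436
5d	5	H	H	3,4,5-triOMe	C26H31N3O5	2	65	red oil	466
5e	5	CH3	H	phenyl	C24H27N3O2	2	65	orange oil	390
5f	5	CH3	H	4-OMe	C25H29N3O3	2	70	orange oil	420
5g	5	CH3	H	3,4-diOMe	C26H31N3O4	2	63	orange oil	450
5h	5	CH3	H	3,4,5-triOMe	C27H33N3O5	2	68	orange oil	480
5i	5	OCH3	H	phenyl	C24H27N3O3	2	77	red oil	406
5j	5	OCH3	H	4-OMe	C25H29N3O4	2	70	red oil	436
5k	5	OCH3	H	3,4-diOMe	C26H31N3O5	2	76	red oil	466
5l	5	OCH3	H	3,4,5-triOMe	C27H33N3O6	2	68	red oil	496
5m	5	Cl	H	phenyl	C23H24ClN3O2	2	74	yellow oil	410
5n	5	Cl	H	4-OMe	C24H26ClN3O3	2	64	yellow oil	440
5o	5	Cl	H	3,4-diOMe	C25H28ClN3O4	2	75	yellow oil	470
5p	5	Cl	H	3,4,5-triOMe	C26H30ClN3O5	2	75	yellow oil	500
6a	6	H	H	phenyl	C23H23N3O2	1	55	orange oil	374
6b	6	H	H	4-OMe	C24H25N3O3	1	65	red oil	NA
6c	6	H	H	3,4,5-triOMe	C26H29N3O5	1	75	brown oil	NA
6d	6	CH3	H	phenyl	C24H25N3O2	1	72	red oil	NA
6e	6	CH3	H	4-OMe	C25H27N3O3	1	64	red oil	NA
6f	6	CH3	Cl	3,4-diOMe	C26H28ClN3O4	1	58	beige solid	482
6g	6	CH3	H	3,4,5-triOMe	C27H31N3O5	1	63	red oil	478
6h	6	OCH3	H	phenyl	C24H25N3O3	1	42	brown oil	NA
6i	6	OCH3	H	4-OMe	C25H27N3O4	1	74	red oil	NA
6j	6	OCH3	Cl	3,4-diOMe	C26H28ClN3O5	1	86	beige solid	NA
6k	6	OCH3	H	3,4,5-triOMe	C27H31N3O6	1	74	red oil	NA
6l	6	Cl	H	phenyl	C23H22ClN3O2	1	55	red oil	NA
6m	6	Cl	H	4-OMe	C24H24ClN3O3	1	51	orange oil	NA
6n	6	Cl	H	3,4-diOMe	C25H26ClN3O4	1	68	orange oil	NA
6o	6	Cl	Cl	3,4-diOMe	C25H25Cl2N3O4	1	88	orange solid	NA
6p	6	Cl	H	3,4,5-triOMe	C26H28ClN3O5	1	85	brown oil	NA
6q	6	CH2CH3	H	phenyl	C25H27N3O2	1	40	brown oil	402
6r	6	CH2CH3	H	4-OMe	C26H29N3O3	1	60	orange oil	432
6s	6	CH2CH3	Cl	3,4-diOMe	C27H30ClN3O4	1	73	beige solid	496
6t	6	CH2CH3	H	3,4,5-triOMe	C28H33N3O5	1	72	orange oil	492
6u	6	F	H	phenyl	C23H22FN3O2	1	89	orange oil	392
6v	6	F	H	4-OMe	C24H24FN3O3	1	77	orange oil	422
6w	6	F	H	3,4-diOMe	C25H26FN3O4	1	75	orange oil	452
6x	6	F	H	3,4,5-triOMe	C26H28FN3O5	1	87	orange oil	482
6y	6	Br	H	phenyl	C23H22BrN3O2	1	95	beige solid	452
6z	6	Br	H	4-OMe	C24H24BrN3O3	1	67	beige solid	482
6aa	6	Br	H	3,4-diOMe	C25H26BrN3O4	1	70	orange oil	512
6ab	6	Br	H	3,4,5-triOMe	C26H28BrN3O5	1	43	orange oil	542
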