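locus_id	gene_id	motif_unit	n_repeats	tm	product_size	polymorphic
MR5	Unigene7776_All	TC	6	55.0	150-177	YES
MR7	Unigene4546_All	CT	6	63.3	150-170	NULL
MR8	Unigene9496_All	TC	6	55.0	150-200	YES
MR13	Unigene26276_All	TC	7	61.4	150-160	YES
MR14	Unigene12899_All	CT	8	61.4	150-165	YES
MR18	Unigene54607_All	TC	10	65.0	250-286	YES
MR20	Unigene9630_All	TG	13	63.3	150-150	NULL
MR23	Unigene51169_All	TC	23	55.0	150-152	NO
MR24	Unigene2731_All	AGC	5	61.4	150-180	NULL
MR31	Unigene16282_All	TTG	5	64.5	150-150	NO
MR32	Unigene10567_All	ACC	5	64.5	150-184	YES
MR39	Unigene7685_All	ATT	6	64.5	250-294	NO
MR40	Unigene18380_All	TCC	6	64.5	150-150	NO
MR41	Unigene11347_All	TCA	7	63.3	150-199	YES
MR47	Unigene9912_All	GGA	7	60.0	300-302	YES
MR51	Unigene826_All	CTT	7	63.3	150-150	YES
MR52	Unigene9209_All	TCC	7	63.3	200-228	YES
MR53	Unigene33994_All	CAT	7	61.4	150-159	YES
MR55	Unigene35088_All	CCT	6	65.0	150-163	YES
MR56	Unigene9209_All	CCT	9	61.4	150-183	YES
MR57	Unigene33873_All	AGG	13	65.0	150-150	NULL
MR58	Unigene51169_All	TCT	24	65.0	300-301	YES
MR59	Unigene1832_All	ATTT	5	65.0	200-204	NULL
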