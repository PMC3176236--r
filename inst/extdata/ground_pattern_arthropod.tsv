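gene	start	end	strand	start_codon	stop_codon	size	intergenic
cox1	1	1532	+			1532	0
cox2	1533	2184	+			652	0
trnK	2185	2246	+			62	0
trnD	2247	2301	+			55	0
atp8	2302	2447	+			146	0
atp6	2448	3094	+			647	0
cox3	3095	3877	+			783	0
trnG	3878	3932	+			55	0
nad3	3933	4271	+			339	0
trnA	4272	4324	+			53	0
trnR	4325	4378	+			54	0
trnN	4379	4437	+			59	0
trnS1	4438	4492	+			55	0
trnE	4493	4547	+			55	0
trnF	4548	4603	-			56	0
nad5	4604	6202	-			1599	0
trnH	6203	6255	-			53	0
nad4	6256	7537	-			1282	0
nad4L	7538	7815	-			278	0
trnT	7816	7869	+			54	0
trnP	7870	7924	-			55	0
nad6	7925	8344	+			420	0
cob	8345	9442	+			1098	0
trnS2	9443	9504	+			62	0
nad1	9505	10396	-			892	0
trnL2	10397	10451	-			55	0
trnL1	10452	10506	-			55	0
rrnL	10507	11502	-			996	0
trnV	11503	11555	-			53	0
rrnS	11556	12245	-			690	0
trnI	12246	12302	+			57	0
trnQ	12303	12368	-			66	0
trnM	12369	12424	+			56	0
nad2	12425	13318	+			894	0
trnW	13319	13386	+			68	0
trnC	13387	13440	-			54	0
trnY	13441	13497	-			57	0
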