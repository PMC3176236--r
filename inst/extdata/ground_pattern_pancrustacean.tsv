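gene	start	end	strand	start_codon	stop_codon	size	intergenic
cox1	1	1532	+			1532	0
trnL2	1533	1587	+			55	0
cox2	1588	2239	+			652	0
trnK	2240	2301	+			62	0
trnD	2302	2356	+			55	0
atp8	2357	2502	+			146	0
atp6	2503	3149	+			647	0
cox3	3150	3932	+			783	0
trnG	3933	3987	+			55	0
nad3	3988	4326	+			339	0
trnA	4327	4379	+			53	0
trnR	4380	4433	+			54	0
trnN	4434	4492	+			59	0
trnS1	4493	4547	+			55	0
trnE	4548	4602	+			55	0
trnF	4603	4658	-			56	0
nad5	4659	6257	-			1599	0
trnH	6258	6310	-			53	0
nad4	6311	7592	-			1282	0
nad4L	7593	7870	-			278	0
trnT	7871	7924	+			54	0
trnP	7925	7979	-			55	0
nad6	7980	8399	+			420	0
cob	8400	9497	+			1098	0
trnS2	9498	9559	+			62	0
nad1	9560	10451	-			892	0
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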