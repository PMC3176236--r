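gene	start	end	strand	start_codon	stop_codon	size	intergenic
cox1	1	1532	+	ATG	TA(A)	1532	0
cox2	1533	2184	+	ATG	T--	652	0
trnK-cuu	2185	2246	+			62	-2
trnD-uau	2245	2299	+			55	1
atp8	2301	2446	+	ATG	TA(A)	146	0
atp6	2447	3093	+	ATA	TA(A)	647	0
cox3	3094	3876	+	ATG	TAA	783	0
trnG-ucc	3877	3931	+			55	0
nad3	3932	4270	+	ATT	TAA	339	8
trnA-ugc	4279	4331	+			53	-4
trnR-ucg	4328	4381	+			54	-7
trnN-guu	4375	4433	+			59	0
trnF-gaa	4434	4489	-			56	1
trnS-gcu	4491	4545	+			55	0
trnE-uuc	4546	4600	+			55	-1
nad5	4600	6198	-	ATA	TAA	1599	-4
trnH-gug	6195	6247	-			53	-1
nad4	6247	7528	-	ATA	TA-	1282	0
nad4L	7529	7806	-	ATG	TA(A)	278	2
trnT-ugu	7809	7862	+			54	5
nad6	7868	8287	+	ATT	TAG	420	993
cob	9281	10378	+	ATG	TAA	1098	4
trnS-uga	10383	10444	+			62	0
rrnS	10445	11134	+			690	0
trnV-uac	11135	11187	+			53	0
rrnL	11188	12183	+			996	12
trnL-uaa	12196	12250	+			55	4
trnL-uag	12255	12309	+			55	0
nad1	12310	13201	+	ATT	T--	892	0
trnP-ugg	13202	13256	+			55	5
trnI-gau	13262	13318	+			57	0
nad2	13319	14212	+	ATA	TAG	894	-3
trnY-gua	14210	14266	-			57	-2
trnQ-uug	14265	14330	-			66	-2
trnM-cau	14329	14384	+			56	2
trnW-uca	14387	14454	+			68	-18
trnC-gca	14437	14491	-			54	1
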