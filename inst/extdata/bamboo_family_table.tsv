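# Published characterization of the 18 moso bamboo GRF genes: ORF length
# (bp, stop included), protein length (aa), isoelectric point, molecular
# weight (Da) and exon count.
name	gene_id	scaffold	loc_start	loc_end	strand	orf_length	protein_length	pi	mol_wt	exons
PeGRF1	PH01000005G1660	PH01000005	1047802	1052107	-	1170	389	9.14	41978.03	4
PeGRF2	PH01000045G1330	PH01000045	869928	873464	+	1008	335	9.04	37271.77	3
PeGRF3	PH01000083G1570	PH01000083	981150	986331	-	1038	345	9.16	37728.96	3
PeGRF4	PH01000152G0440	PH01000152	299152	308034	-	1407	468	6.25	51266.89	6
PeGRF5	PH01000197G1460	PH01000197	930248	936852	+	1179	392	7.71	42011.71	4
PeGRF6	PH01000387G0730	PH01000387	652447	654934	+	1362	453	6.73	49141.86	3
PeGRF7	PH01000513G0530	PH01000513	390562	394641	+	1206	401	8.34	43195.84	7
PeGRF8	PH01000842G0540	PH01000842	394216	395977	+	639	212	9.3	22503.55	3
PeGRF9	PH01001096G0260	PH01001096	234426	237322	+	1113	370	6.21	40368.06	3
PeGRF10	PH01001291G0040	PH01001291	25862	27620	-	939	312	8.47	34018.72	2
PeGRF11	PH01001304G0330	PH01001304	285822	288315	-	513	170	9.32	18478.01	2
PeGRF12	PH01001605G0350	PH01001605	262844	268296	+	1656	551	8.63	58800.40	8
PeGRF13	PH01002169G0420	PH01002169	248859	249908	+	651	216	9.57	22808.98	3
PeGRF14	PH01002618G0290	PH01002618	154780	159948	+	1335	444	6.72	48549.03	5
PeGRF15	PH01002701G0020	PH01002701	4592	8886	-	783	260	4.92	27787.69	3
PeGRF16	PH01003592G0180	PH01003592	111903	116228	+	1239	412	9.29	46690.54	4
PeGRF17	PH01005386G0020	PH01005386	5903	9192	+	1236	411	9.3	46270.16	4
PeGRF18	PH01087379G0010	PH01087379	32	1145	-	996	331	8.24	36416.32	2
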