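gene_name	locus_id	chrom	strand	location	cds_length
BrVQ1-1	Bra025998	A06	-	6,588,703–6,588,999	297
BrVQ1-2	Bra016616	A08	+	19,301,503–19,301,796	294
BrVQ3-1	Bra025892	A06	-	8,759,573–8,760,265	693
BrVQ3-2	Bra012276	A07	+	8,889,633–8,890,172	540
BrVQ4	Bra030082	A07	+	6,712,561–6,713,295	735
BrVQ5	Bra035492	A08	-	7,791,236–7,791,901	666
BrVQ8	Bra033934	A02	-	108,00,121–10,800,534	414
BrVQ9-1	Bra035028	A07	-	21,850,607–21,851,491	885
BrVQ9-2	Bra008356	A02	-	14,998,946–14,999,815	870
BrVQ10-1	Bra008359	A02	+	15,035,463–15,035,777	315
BrVQ10-2	Bra003642	A07	-	14,203,152–14,203,469	318
BrVQ10-3	Bra035035	A07	+	21,882,989–21,883,270	282
BrVQ11-1	Bra035182	A07	+	22,479,008–22,479,511	504
BrVQ11-2	Bra003566	A07	-	13,824,994–13,825,515	522
BrVQ11-3	Bra008473	A02	+	15,858,716–15,859,210	495
BrVQ12	Bra039937	A09	+	31,714,821–31,715,237	417
BrVQ14-1	Bra023004	A03	+	8,183,495–8,184,808	1314
BrVQ14-2	Bra017329	A04	+	15,346,657–15,347,685	1029
BrVQ14-3	Bra005358	A05	-	5,012,814–5,014,478	1185
BrVQ15	Bra016956	A04	-	17,404,492–17,405,181	690
BrVQ16-1	Bra000216	A03	+	9,940,673–9,941,098	426
BrVQ16-2	Bra004604	A05	+	1,001,763–1,002,185	423
BrVQ18-1	Bra004825	A05	+	1,984,033–1,984,575	543
BrVQ18-2	Bra037658	A04	+	18,293,805–18,294,347	543
BrVQ19-1	Bra027262	A05	+	20,006,387–20,007,064	678
BrVQ19-2	Bra021096	A01	+	23,997,911–23,998,561	651
BrVQ20	Bra037588	A01	+	22,145,216–22,146,079	864
BrVQ21-1	Bra037569	A01	+	22,005,523–22,006,176	654
BrVQ21-2	Bra022345	A05	+	182,87,618–18,288,268	651
BrVQ21-3	Bra001716	A03	-	18,018,055–18,018,699	645
BrVQ22-1	Bra023849	A01	+	2,0411,389–20,411,979	591
BrVQ22-2	Bra041035	Scaffold000402	-	11,806–12,390	585
BrVQ23-1	Bra007265	A09	-	28,278,350–28,278,799	450
BrVQ23-2	Bra014675	A04	+	2,158,610–2,159,095	486
BrVQ23-3	Bra014674	A04	+	2,155,783–2,156,247	465
BrVQ24-1	Bra007279	A09	+	28,339,520–28,340,206	687
BrVQ24-2	Bra014665	A04	-	2,098,440–2,099,141	702
BrVQ25-1	Bra007373	A09	+	28,879,454–28,879,999	546
BrVQ25-2	Bra014594	A04	-	1,651,117–1,651,650	534
BrVQ26-1	Bra007505	A09	+	29,533,410–29,533,874	465
BrVQ26-2	Bra014514	A04	-	1,142,901–1,143,341	441
BrVQ26-3	Bra003400	A07	+	13,026,327–13,029,056	846
BrVQ27	Bra039565	A01	-	11,929,165–11,929,719	555
BrVQ28	Bra013438	A01	+	5,666,359–5,666,979	621
BrVQ29-1	Bra010608	A08	+	15,506,771–15,507,115	345
BrVQ29-2	Bra017849	A03	+	30,916,676–30,917,020	345
BrVQ30-1	Bra010666	A08	+	15,875,832–15,876,719	888
BrVQ30-2	Bra011838	A01	-	282,249–283,121	873
BrVQ31	Bra005995	A03	+	1,534,982–153,5506	525
BrVQ32-1	Bra022063	A02	+	18,984,720–18,985,412	693
BrVQ32-2	Bra024996	A06	-	24,596,158–24,596,844	687
BrVQ33-1	Bra003032	A10	+	5,893,364–5,894,047	684
BrVQ33-2	Bra022675	A02	-	8,093,063–8,093,788	726
BrVQ34-1	Bra024362	A06	+	15,221,647–15,222,738	1092
BrVQ34-2	Bra037806	A09	+	3,657,352–3,658,311	960
BrVQ34-3	Bra031876	A02	+	27,356,488–27,357,465	978
BrVQ35	Bra006328	A03	-	3,034,196–3,038,533	1707
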