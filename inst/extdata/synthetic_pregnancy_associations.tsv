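phenotype_id	group	a	b	c	d	p
preg_dx_01	pregnancy_childbirth_puerperium	512	74210	618	75102	0.002
preg_dx_02	pregnancy_childbirth_puerperium	289	74433	302	75418	0.62
preg_dx_03	pregnancy_childbirth_puerperium	1045	73677	1050	74670	0.86
preg_dx_04	pregnancy_childbirth_puerperium	178	74544	210	75510	0.12
preg_dx_05	pregnancy_childbirth_puerperium	93	74629	101	75619	0.58
preg_dx_06	pregnancy_childbirth_puerperium	731	73991	748	74972	0.74
preg_dx_07	pregnancy_childbirth_puerperium	406	74316	371	75349	0.19
preg_dx_08	pregnancy_childbirth_puerperium	152	74570	170	75550	0.37
preg_dx_09	pregnancy_childbirth_puerperium	845	73877	812	74908	0.41
preg_dx_10	pregnancy_childbirth_puerperium	64	74658	80	75640	0.21
preg_dx_11	pregnancy_childbirth_puerperium	920	73802	918	74802	0.95
preg_dx_12	pregnancy_childbirth_puerperium	233	74489	259	75461	0.28
preg_dx_13	pregnancy_childbirth_puerperium	57	74665	49	75671	0.43
preg_dx_14	pregnancy_childbirth_puerperium	1310	73412	1305	74415	0.89
preg_dx_15	pregnancy_childbirth_puerperium	488	74234	507	75213	0.61
preg_dx_16	pregnancy_childbirth_puerperium	210	74512	196	75524	0.46
preg_dx_17	pregnancy_childbirth_puerperium	119	74603	134	75586	0.38
preg_dx_18	pregnancy_childbirth_puerperium	676	74046	641	75079	0.32
preg_dx_19	pregnancy_childbirth_puerperium	388	74334	426	75294	0.20
preg_dx_20	pregnancy_childbirth_puerperium	341	74381	390	75330	0.009
preg_dx_21	pregnancy_childbirth_puerperium	88	74634	92	75628	0.79
preg_dx_22	pregnancy_childbirth_puerperium	542	74180	531	75189	0.71
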