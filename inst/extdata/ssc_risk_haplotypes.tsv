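snp_id	chrom	start	end	locus_name
rs2205960	chr1	173222336	173287411	TNFSF4
rs10488631	chr7	128945562	129071820	IRF5
rs11642873	chr16	85956661	85958099	IRF8
rs2056626	chr1	167448647	167467063	CD247
rs3790567	chr1	67340123	67361333	IL12RB2
rs3821236	chr2	191035723	191071078	STAT4
rs77583790	chr3	159907604	159976265	SCHIP1-IL12A
rs9373839	chr6	106181815	106339294	ATG5
rs5029939	chr6	137849452	137921300	TNFAIP3
rs1378942	chr15	74751897	74821981	CSK
rs2305743	chr19	18068862	18092777	IL12RB1
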