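sample	group	raw_reads	clean_reads	q30_pct	gc_pct	total_mapped	uniquely_mapped
DP1	DP	184408224	181065646	96.5	53.07	156206414	143152662
DP2	DP	155782622	152534698	96.53	53.23	131660504	120711885
DP3	DP	162876662	158253090	96.35	53.07	132600127	121998364
LP1	LP	160155930	156985398	96.53	53.17	135755839	122863727
LP2	LP	139072986	135208918	96.35	50.51	115961807	107999673
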