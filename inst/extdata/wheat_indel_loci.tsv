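locus_id	chrom	emmer_start	emmer_end	emmer_length	bw_start	bw_end	bw_length	type
5B_1	5B	566939353	567135082	195730	561057394	561064945	7552	deletion_in_b
3B_1	3B	774200469	774452950	252482	760803787	760805537	1751	deletion_in_b
5B_2	5B	516702290	516721374	19085	511383608	511385023	1416	deletion_in_b
5B_3	5B	363487255	363551431	64177	349934346	349934349	4	deletion_in_b
5B_4	5B	587350647	587364130	13484	581381548	581381551	4	deletion_in_b
3B_2	3B	284755035	284771490	16456	286353814	286353819	6	deletion_in_b
3B_3	3B	493386824	493410158	23335	482234389	482234390	2	deletion_in_b
3B_4	3B	538946011	540047920	1101910	527682008	527682029	22	deletion_in_b
3B_5	3B	606914695	606946995	32301	596314588	596314620	33	deletion_in_b
5B_5	5B	610009239	610050693	41455	603942312	603952982	10671	introgression
5B_6	5B	84661892	85585936	924045	81624361	82045980	421620	copy_number_variation
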