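# Contigs reported for the ODA14 xenograft amplicons: ordered junctions
# (arm labels), per-junction microhomology (bp), fragment lengths (bp) and
# distances between fragments in the normal genome (kb), as published.
# Values are transcribed verbatim, including the internally inconsistent
# fragment count of contig 10 and the 8 microhomology values printed for the
# 9 junctions of contig 18.
passage	contig	junctions	mh	frag_lengths	distances_kb
p2	1	a11b a16b	3,0	61	170
p2	2	a14b a36b	0,0	66	105
p2	3	a15b a34b	0,0	22	60
p2	4	a55b a47b	0,0	28	815
p2	5	a2b a21b b23a	0,0,0	222,1386	782,10
p2	6	b18a a19b a53b	6,2,1	36,64	na,1232
p2	7	b8a a9b b13a a12b a5b a26b	2,1,1,0,0,0	128,160,293,316,326	116,1.5,719,188,737
p2/p4	8	a24b b7a	3,0	290	190
p2/p4	9	a4b b3a a6b a22b b31a a32b	2,1,0,4,2,2	108,2118,67	0.14,376,235
p2/p4	10	b39a a38b b30a a29b b10a	0,0,2,0,5	386,171,126,329,244,348	17,197,6,333,10,369
p4	11	a73b a83b a35b	2,2,3	71,224	565,21
p4	12	a74b a85b	0,2	30	na
p4	13	a75b a69b	2,1	72	621
p4	14	a78b a77b	2,0	35	12
p4	15	b92a b98a	0,0	20	91
p4	16	a82b a80b	0,0	109	18
p4	17	a88b b81a	2,2	948	na
p4	18	b91a b99a b103a a102b a104b b94a b101a b100a b87a	2,0,2,1,0,2,0,0	257,35856,14115,1258,1168,4331,21471,72238	2077,3297,998,1000,1956,949,2588,na
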