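# Breakpoint clusters reported for chromosome 7 of the ODA14 oligodendroglioma
# xenograft at passage 2 (dmin state). Each row: ordered member arm labels,
# the printed gaps (bp) between consecutive members, the position of the first
# member, and the printed total length. Positions of all members reconstruct
# as anchor + cumulative gaps.
cluster	members	gaps	anchor	printed_span
A	a3 a4 b12 a5 a6	141,1192,316,469	54520243	2118
B	a7 a8 a9 a10 a11 a12 a13	821,128,246,353,656,293	54558285	2497
C	a16 b11	61	54668755	61
D	a19 a18 b36	36,91	54697888	127
E	a21 b2	222	54738501	222
F	a22 a23 b5 b6 a24 a25 a26	1,41,17,34,10,265	54748976	376
G	a27 a28	1823	54880905	1823
H	a29 a30	244	54928591	244
I	a31 a32 a33	386,921	55064954	1307
J	b15 a34 b8 b4 b3 a35	22,1792,306,108,40	55123258	2227
K	b24 b7	290	55202557	290
L	b14 a36 b17	66,1461	55206654	1527
M	a37 b13 b9	30,160	55241284	190
N	b23 b33 b35 b21 b26	331,165,885,613	55257873	1999
O	b39 b32 b25 a38 a39	171,5,82,126	55262169	384
P	b30 b38 b37	329,505	55268502	834
Q	b10 b29 b31	348,1133	55278611	1481
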