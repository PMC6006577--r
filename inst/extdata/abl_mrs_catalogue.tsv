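site	mrs	seq16	strand16	start16	end16	seq8	strand8	start8	end8	distance	location
1	1-1	ATTGTAACCATATCTC	C	26055	26070	AATAATAA	C	26118	26125	+47	Intron 1
1	1-2	ATCATAACTTAGCAAC	C	26613	26628	AATAACAA	W	26565	26572	-40	Intron 1
2	2	AAAAAAATTTTGTACC	C	29601	29616	AATAATAA	C	29629	29636	+12	Intron 1
3	3-1	ATAATAATTATACAAC	C	80698	80713	AATAATAA	W	80726	80733	+12	Intron 1
3	3-1	AATATAAATAAAGTGC	W	80732	80747	AATAATAA	W	80726	80733	Overlap	Intron 1
3	3-2	ATTGTAACTAAGGTTC	C	81458	81473	AATAACAA	C	81422	81429	-28	Intron 1
4	4	ATAATAATAAAGAGAT	W	99259	99274	AATAATAA	W	99261	99268	Overlap	Intron 1
4	4	AATATAATCAACTGAC	W	99447	99462	AATAATAA	W	99261	99268	-178	Intron 1
5	5	ATAAAAAGGAAGATTC	W	105498	105513	AATAATAA	C	105616	105623	+102	Intron 1
6	6	AAAAAAAAAAAGACTC	C	108315	108330	AATAATAA	C	108484	108491	+153	Intron 1
6	6	AAAAAAAAAAAGACTC	C	108315	108330	AATAATAA	C	108487	108494	+156	Intron 1
6	6	AAAAAAAAAAAGACTC	C	108315	108330	AATAATAA	C	108490	108497	+159	Intron 1
7	7	AATGTAACAGAGAGCC	C	117122	117137	AATAACAA	W	117343	117350	+205	Intron 1
8	8	AAAATAAACATATACC	W	119757	119772	AATAATAA	W	119739	119746	-10	Intron 1
9	9	AAAGTAAAATTGAAAG	C	133546	133561	AATAACAA	W	133810	133817	+248	Intron 1
10	10	ATTACAAGTTTGGTAC	C	144212	144227	AATAATAA	C	143996	144003	-208	Intron 3
11	11	ATAAAAACAAAGAAGC	C	163018	163033	AATAACAA	W	163048	163055	+14	Intron 7
12	12	AAAATAATAATGGCCA	W	167856	167871	AATAATAA	W	167858	167865	Overlap	Intron 10
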