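label	start	end	strand
Exon 1	1	1200	W
Intron 1	1201	141200	W
Exon 2	141201	141400	W
Intron 2	141401	143400	W
Exon 3	143401	143600	W
Intron 3	143601	146600	W
Exon 4	146601	146800	W
Intron 4	146801	149800	W
Exon 5	149801	150000	W
Intron 5	150001	153000	W
Exon 6	153001	153200	W
Intron 6	153201	156200	W
Exon 7	156201	156400	W
Intron 7	156401	164400	W
Exon 8	164401	164600	W
Intron 8	164601	165600	W
Exon 9	165601	165800	W
Intron 9	165801	166800	W
Exon 10	166801	167000	W
Intron 10	167001	169000	W
Exon 11	169001	173795	W
SAR1	129000	134000	W
BCRA	25500	30200	W
BCRB	80000	82000	W
BCRC	127500	134500	W
region_of_study	128301	132000	W
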