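# Saccharomyces cerevisiae S288C genome annotation, sacCer2 assembly (SGD/UCSC).
# Chromosome lengths from the sacCer2 chromInfo table; centromere midpoints
# from the SGD CEN1-CEN16 annotations; rDNA is the RDN1 locus on chrXII.
# Non-nuclear sequences (chrM, 2micron) are listed as excluded, not as rows.
#rdna	chrXII	451575	468931
#excluded	chrM	2micron
chrom	length	cen_mid	copy_number
chrI	230208	151524	2
chrII	813178	238265	2
chrIII	316617	114443	2
chrIV	1531919	449766	2
chrV	576869	152046	2
chrVI	270148	148569	2
chrVII	1090947	497100	2
chrVIII	562643	105761	2
chrIX	439885	355803	2
chrX	745742	436366	2
chrXI	666454	440188	2
chrXII	1078175	150888	2
chrXIII	924429	268090	2
chrXIV	784333	628817	2
chrXV	1091289	326643	2
chrXVI	948062	556015	2
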