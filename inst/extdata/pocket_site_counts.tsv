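# Pocket-located divergent-site counts and total selected sites for the ten
# published chemokine-receptor comparisons (CXCR4 reference). Totals are the
# per-comparison row counts of the published site table; the E1 total is
# ambiguous in the source (text says "about 11-14 sites per group" while the
# table block lists 9 rows) and is recorded as listed.
comparison	class	pocket_sites	total_sites
CCRL1	decoy	2	14
CCRL2	decoy	2	13
CCBP2	decoy	0	11
CXCR7	decoy	1	14
DARC	decoy	1	14
E1	viral	3	9
ORF74	viral	2	13
UL33	viral	5	14
betaHV	viral	3	11
pox	viral	4	14
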