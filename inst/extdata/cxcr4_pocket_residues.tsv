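# CXCR4 ligand-binding pocket residues (author numbering, 3ODU chain A),
# as annotated in the published site table for the ten receptor comparisons.
residue
31
38
94
102
112
116
120
121
123
171
190
203
207
208
248
256
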