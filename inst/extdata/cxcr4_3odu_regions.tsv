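# Topological regions of human CXCR4, PDB 3ODU chain A, author numbering.
# TM boundaries reconstructed from GPCRDB-style structural elements via the
# Ballesteros-Weinstein anchors of the receptor (N56=1.50, D84=2.50,
# R134=3.50, W161=4.50, P211=5.50, P254=6.50, P299=7.50) together with the
# region membership of boundary residues (Q66 in ICL1, V112 in TM3, C218 in
# ICL3, L244 in TM6, W283 in TM7). The EXCLUDE row covers the fused T4
# lysozyme insert, numbered in the 1000s in this entry. The C range is also
# excluded from the intracellular-center computation (cytosol-extending
# tail, residues 303-328).
label	start	end
N	27	39
TM1	40	65
ICL1	66	77
TM2	78	100
ECL1	101	111
TM3	112	132
ICL2	133	155
TM4	156	174
ECL2	175	197
TM5	198	217
ICL3	218	243
TM6	244	267
ECL3	268	280
TM7	281	302
C	303	328
EXCLUDE	1000	1200
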