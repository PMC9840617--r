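# Per-isotype conserved group I intron consensus strings of plastid tRNAs
# (transcription of the published per-isotype consensus table into the
# package's ASCII run-length notation: tokens joined by "-", "x" an
# unconstrained position, "x_3_" a fixed wildcard run, "x_4:5_" a variable
# run, "A/G" a degenerate position).
# Isotypes printing several consensus lines (Cys, Glu, Ser, Tyr) keep one
# row per line; isotypes without a conserved intron carry "Not found".
isotype	line	consensus
Ala	1	A-U-U-G-G-G-U-C-G-U-U-G-C-G-A-U-U-A-C-G-G-x-G-U-x-U-G-G-A-U-G-U-C-U-A-A-U-U-G
Arg	1	Not found
Asn	1	Not found
Asp	1	Not found
Cys	1	G-C-G-C-G-C-C-C-A-A-U-G-U-U-U-U-U-x-C-A-G-x-G-G-A-x-G-U-x-C-A-U-C-A-U-G-x-A-A-U-C-A-A-A-A-x_3_-U-x-A-U
Cys	2	G-x_8_-U-x-U-x_4:5_-C-A-G/A-x_3_-A-x_2_-U-C-x_2_-U-x_5_-A-A-U-x-A-x_2_-A-x_2:3_-U-U-G-A-U-C/U-x_2_-U-U-U-A
Gln	1	Not found
Glu	1	A-U-U-G-C-G-U-C-G-U-U-G-U-G-C-x-G-G-G-C-U-G-U-G-A-x-G-G-C-U-C-U-C-A
Glu	2	U-x_2_-U/C-G-U/C-x-G-x-U-G-x-G-x_8_-C-U
Gly	1	G-x-G-x-C-x_3_-G-C-x_2_-U-U-x_1:5_-C-x_3_-U-A-U-A-x_2_-C
His	1	Not found
Ile	1	A/C-G/U-U-G-C-G-x-C-A/G-U-G-U-U/G-U/G-U/C-U/C-U-x_1:3_-C-x-G-x_3_-A/G-G-U/G-x_2_-A/C-U-C/U-A-x_2_-U/G-x-C-A-x_5_-A/U-x_4_-U
Leu	1	A-A-C-x_5_-A-A-x-U-x_3_-A-G-x-A-x_2_-A-x_2_-A-A
Lys	1	A-G-U-G-C-G-x-C-U-x_4_-U-x-U-U-U-x-A-C-A-C-A-U-U-U-x_2_-A-U-G-A-A
Met	1	U-x-U-G-x-A-x_2_-A-G-A-G-x-U-U-U-x_9:10_-C-G-A-C-U-x_2_-A-A-U-A
Phe	1	C-x_2_-G-C-G-C-C-A-A-U-G-x_1:2_-U-U-x-U-C-A-x_2_-G-x-A-G-U-C-x-A-U-x-A-U-G-x-A-A-U-x-A-x-A-A-A-x-A
Pro	1	Not found
Ser	1	A-C-G-U-U-x-A-A-A-x-A-x-U-x_2:7_-G-U-C-G-A-A-C-C-C-C
Ser	2	A-x_3_-A-x_2:5_-G-U-C-G-A-A-C-C-C
Ser	3	A-x_2:7_-A-U-x_2_-A-C-x_4_-G-x_1:2_-C-x_2_-C
Ser	4	C-x_5_-A-A-x_6_-A-x_8_-U-C-x_5_-C-x_1:2_-U-x_2_-A-x_3_-C
Thr	1	A-U-U-G-C-G-U-C-G-U-U-G-U-G-C-C-U-G-G-G-C-U-G-U-G-A-G-G-G-C-U-C-U-C-A-G-C-C-A-C-A-U-G-G-A-U-A-G-U-U-C
Trp	1	Not found
Tyr	1	G-U-U-G-G-G-U-x-U-U/C-C/U-U-x_2_-A-A-C-A-G-U-U-C-A-A-A-U-x-A-U-U-U-U-G-A-U-A-A-U-A-A-x-A-x-C-U-U-U-G-A-U-C-U-G-U-U-x-U-A
Tyr	2	G-x-U-U-U-U-x_4_-C-x_5_-A-x_5_-U
Val	1	Not found
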