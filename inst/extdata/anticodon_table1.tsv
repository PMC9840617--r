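# Pooled anticodon census of 5,959 plastid genomes (verbatim transcription
# of the published pooled table; counts as printed).
# Notes:
# - The running text reports a pooled total of 215,966 tRNA genes; the
#   printed cells sum to 214,383. This fixture follows the printed table.
# - The running text quotes "UCG and GAU" spacer-tRNA percentages of
#   5.13/4.98; the printed Ala row carries 11,017 under UGC (not UCG).
#   Treated as a typo for UGC in the text; the fixture is not altered.
# - The suppressor CUA cell is printed blank ("did not find any"); stored
#   here as 0.
isotype	anticodon	count
Ala	AGC	214
Ala	GGC	203
Ala	CGC	1
Ala	UGC	11017
Arg	ACG	10927
Arg	GCG	0
Arg	CCG	304
Arg	UCG	103
Arg	CCU	12
Arg	UCU	5729
Asn	AUU	2
Asn	GUU	11018
Asp	AUC	399
Asp	GUC	6122
Cys	ACA	224
Cys	GCA	6156
Gln	CUG	0
Gln	UUG	6242
Glu	CUC	0
Glu	UUC	5925
Gly	ACC	204
Gly	GCC	4917
Gly	CCC	0
Gly	UCC	5684
His	AUG	405
His	GUG	7148
Ile	AAU	22
Ile	GAU	10695
Ile2	CAU	10575
Ile	UAU	5
Leu	AAG	1
Leu	GAG	42
Leu	CAG	6
Leu	UAG	5745
Leu	CAA	10686
Leu	UAA	5546
Lys	CUU	7
Lys	UUU	5312
Met	CAU	11741
fMet	CAU	709
Phe	AAA	207
Phe	GAA	5982
Pro	AGG	2
Pro	GGG	817
Pro	CGG	0
Pro	UGG	5883
Ser	AGA	203
Ser	GGA	5520
Ser	CGA	173
Ser	UGA	5174
Ser	ACU	0
Ser	GCU	5980
Thr	AGU	1
Thr	GGU	5703
Thr	CGU	454
Thr	UGU	5669
Trp	CCA	5955
Tyr	AUA	6
Tyr	GUA	5964
Val	AAC	399
Val	GAC	10687
Val	CAC	200
Val	UAC	4748
Sec	UCA	204
Pyl	CUA	197
Sup	CUA	0
Sup	UUA	205
Sup	UCA	2
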