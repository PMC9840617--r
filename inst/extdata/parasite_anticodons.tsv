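# Anticodon repertoires of the eight parasitic/heterotrophic plastomes with
# fewer than ten tRNA genes, as printed per species (isotype labels as
# printed; duplicated anticodons within a species kept).
species	anticodon	isotype
Asarum minus	UUU	Lys
Asarum minus	UUG	Gln
Asarum minus	GCU	Ser
Asarum minus	UCC	Gly
Asarum minus	UCU	Arg
Gastrodia elata	UUG	Gln
Gastrodia elata	GCA	Cys
Gastrodia elata	UUC	Glu
Gastrodia elata	CAU	fMet
Gastrodia elata	CCA	Trp
Sciaphila densiflora	UUG	Gln
Sciaphila densiflora	CAU	Ile
Sciaphila densiflora	CCA	Trp
Sciaphila densiflora	CAU	fMet
Sciaphila densiflora	UUC	Glu
Sciaphila densiflora	GCA	Cys
Epirixanthes elongata	CCA	Trp
Epirixanthes elongata	CAU	fMet
Epirixanthes elongata	UUG	Gln
Epirixanthes elongata	GUC	Asp
Epirixanthes elongata	GUA	Tyr
Epirixanthes elongata	UUC	Glu
Burmannia oblonga	UUG	Gln
Burmannia oblonga	GCA	Cys
Burmannia oblonga	GUA	Tyr
Burmannia oblonga	UCC	Glu
Burmannia oblonga	CAU	fMet
Burmannia oblonga	GUG	His
Burmannia oblonga	CAU	Ile
Lecanorchis japonica	UUG	Gln
Lecanorchis japonica	GCA	Cys
Lecanorchis japonica	GUC	Asp
Lecanorchis japonica	CAU	fMet
Lecanorchis japonica	GAA	Phe
Lecanorchis japonica	CAU	Ile
Lecanorchis japonica	GUU	Asn
Lecanorchis kiusiana	UUG	Gln
Lecanorchis kiusiana	GCA	Cys
Lecanorchis kiusiana	GUC	Asp
Lecanorchis kiusiana	UUC	Glu
Lecanorchis kiusiana	CAU	fMet
Lecanorchis kiusiana	GAA	Phe
Lecanorchis kiusiana	CAU	Ile
Lecanorchis kiusiana	GUU	Asn
Selaginella tamariscina	GUG	His
Selaginella tamariscina	GUC	Asp
Selaginella tamariscina	GUA	Tyr
Selaginella tamariscina	UUC	Glu
Selaginella tamariscina	GUU	Asn
Selaginella tamariscina	CCA	Trp
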