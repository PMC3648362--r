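1	LRF	LRF	Gene or Genome	Entity|BiologicalEntity|Gene|LRF
1	c-Jun	c-Jun	Gene or Genome	Entity|BiologicalEntity|Gene|c-Jun
1	c-fos	c-fos	Gene or Genome	Entity|BiologicalEntity|Gene|c-fos
1	Program	Program	Biologic Function	Entity|Process|Program
1	Liver	Liver	Body Part, Organ, or Organ Component	Entity|BiologicalEntity|Anatomy|Liver
1	Regeneration	Regeneration	Biologic Function	Entity|Process|BiologicalProcess|Regeneration
2	LRF	LRF	Gene or Genome	Entity|BiologicalEntity|Gene|LRF
2	LRF	LRF	Gene or Genome	Entity|BiologicalEntity|Gene|LRF
2	c-Jun	c-Jun	Gene or Genome	Entity|BiologicalEntity|Gene|c-Jun
2	c-fos	c-fos	Gene or Genome	Entity|BiologicalEntity|Gene|c-fos
2	Liver	Liver	Body Part, Organ, or Organ Component	Entity|BiologicalEntity|Anatomy|Liver
2	Cell	Cell	Cell	Entity|BiologicalEntity|CellStructure|Cell
2	growth	growth	Biologic Function	Entity|Process|BiologicalProcess|growth
3	LRF	LRF	Gene or Genome	Entity|BiologicalEntity|Gene|LRF
3	LRF	LRF	Gene or Genome	Entity|BiologicalEntity|Gene|LRF
3	c-Jun	c-Jun	Gene or Genome	Entity|BiologicalEntity|Gene|c-Jun
3	c-fos	c-fos	Gene or Genome	Entity|BiologicalEntity|Gene|c-fos
3	Liver	Liver	Body Part, Organ, or Organ Component	Entity|BiologicalEntity|Anatomy|Liver
3	Cell	Cell	Cell	Entity|BiologicalEntity|CellStructure|Cell
3	LRF-1	LRF-1	Gene or Genome	Entity|BiologicalEntity|Gene|LRF-1
3	Transition	Transition	Biologic Function	Entity|Process|BiologicalProcess|Transition
3	Complexes	Complexes	Amino Acid, Peptide, or Protein	Entity|ChemicalEntity|Complexes
3	Complexes	Complexes	Amino Acid, Peptide, or Protein	Entity|ChemicalEntity|Complexes
4	LRF	LRF	Gene or Genome	Entity|BiologicalEntity|Gene|LRF
4	Promoter	Promoter	Nucleotide Sequence	Entity|BiologicalEntity|NucleicAcidFeature|Promoter
4	C-Complex	C-Complex	Amino Acid, Peptide, or Protein	Entity|ChemicalEntity|Complexes|C-Complex
5	LRF	LRF	Gene or Genome	Entity|BiologicalEntity|Gene|LRF
5	Promoter	Promoter	Nucleotide Sequence	Entity|BiologicalEntity|NucleicAcidFeature|Promoter
5	Combination	Combination	Activity	Entity|ConceptualEntity|Combination
5	JUNProtein	JUNProtein	Amino Acid, Peptide, or Protein	Entity|ChemicalEntity|Protein|JUNProtein
5	Protein	Protein	Amino Acid, Peptide, or Protein	Entity|ChemicalEntity|Protein
5	Element	Element	Nucleotide Sequence	Entity|BiologicalEntity|NucleicAcidFeature|Element
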