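a	b	kind
BiologicalEntity	Entity	is_a
ChemicalEntity	Entity	is_a
Process	Entity	is_a
ConceptualEntity	Entity	is_a
Gene	BiologicalEntity	is_a
Anatomy	BiologicalEntity	is_a
CellStructure	BiologicalEntity	is_a
NucleicAcidFeature	BiologicalEntity	is_a
Protein	ChemicalEntity	is_a
Complexes	ChemicalEntity	is_a
BiologicalProcess	Process	is_a
Program	Process	is_a
Combination	ConceptualEntity	is_a
LRF	Gene	is_a
c-Jun	Gene	is_a
c-fos	Gene	is_a
LRF-1	Gene	is_a
Liver	Anatomy	is_a
Cell	CellStructure	is_a
Promoter	NucleicAcidFeature	is_a
Element	NucleicAcidFeature	is_a
JUNProtein	Protein	is_a
C-Complex	Complexes	is_a
Regeneration	BiologicalProcess	is_a
growth	BiologicalProcess	is_a
Transition	BiologicalProcess	is_a
LRF	c-Jun	metathesaurus_related
LRF	c-fos	metathesaurus_related
c-Jun	c-fos	metathesaurus_related
LRF	LRF-1	metathesaurus_related
JUNProtein	c-Jun	metathesaurus_related
Liver	Regeneration	semantic_network_related
Cell	growth	semantic_network_related
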