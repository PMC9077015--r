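# SYNTHETIC stand-in for a formula-level systems-pharmacology pathway
# annotation (the original supplementary annotation is not public).
# Constructed to reproduce the published overlap structure against the
# bundled metabonomics pathway results: it contains the six overlapping
# metabolic pathways (in KEGG spellings) and omits the four published
# non-overlapping ones. One pathway name per line.
Aminoacyl-tRNA biosynthesis
Glycolysis / Gluconeogenesis
Glycine, serine and threonine metabolism
Valine, leucine and isoleucine biosynthesis
Arginine and proline metabolism
Pyruvate metabolism
Citrate cycle (TCA cycle)
Oxidative phosphorylation
Pentose phosphate pathway
Starch and sucrose metabolism
Glycerolipid metabolism
Glycerophospholipid metabolism
Sphingolipid metabolism
Fatty acid biosynthesis
Steroid hormone biosynthesis
Primary bile acid biosynthesis
Bile secretion
Tryptophan metabolism
Tyrosine metabolism
Phenylalanine metabolism
Cysteine and methionine metabolism
beta-Alanine metabolism
Purine metabolism
Pyrimidine metabolism
Arachidonic acid metabolism
Linoleic acid metabolism
Drug metabolism - cytochrome P450
Metabolism of xenobiotics by cytochrome P450
MAPK signaling pathway
PI3K-Akt signaling pathway
Wnt signaling pathway
PPAR signaling pathway
Chemokine signaling pathway
GnRH signaling pathway
Calcium signaling pathway
cAMP signaling pathway
Insulin signaling pathway
Thyroid hormone synthesis
Neuroactive ligand-receptor interaction
Apoptosis
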