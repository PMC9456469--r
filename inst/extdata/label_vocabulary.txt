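acetylation
activation
acylation
adhesion
angiogenesis
apoptotic
biosynthetic
blood
catabolic
cell
cellular
chondrocyte
chromatin
commitment
compound
cycle
cytokine
damage
development
differentiation
division
endopeptidase
epigenetic
erythroid
growth
hematopoietic
hemopoiesis
histone
homeostasis
immune
inflammatory
kinase
leukocyte
lineage
maturation
membrane
metabolic
methylation
migration
myeloid
negative
nuclear
pathway
phosphate-containing
phosphorylation
population
positive
process
proliferation
protein
receptor
regulation
repair
response
signaling
stem
stress
transcription
vessel
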