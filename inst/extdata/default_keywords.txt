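myeloid
leukocyte
differentiation
chromatin
acetylation
acylation
angiogenesis
immune
kinase
epigenetic
endopeptidase
chondrocyte
p53
hemopoiesis
hematopoietic
cytokine
phosphorylation
stem
growth
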