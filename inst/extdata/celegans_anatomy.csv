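# Partial anatomy table for the adult C. elegans hermaphrodite:
# cell -> tissue, nuclei per (possibly syncytial) cell, C-value per nucleus.
# Compiled from WormAtlas and the WormBase anatomy ontology (WBbt);
# syncytial nuclei counts cross-checked against Shemer & Podbilewicz (2000),
# Table 1. This fixture covers the cells with well-attested counts used in
# tests and examples; it is NOT a complete census of the 959 somatic cells.
# Conventions:
#  - intestinal cells are recorded as nuclei=1 at the young-adult C-value 32
#    (i.e. 16 diploid genome equivalents per cell); where a cell is
#    binucleate in a given animal, express it explicitly as nuclei=2 with the
#    per-nucleus C-value instead.
#  - "cuticle" is extracellular: somatic, zero nuclei (ploidy_c ignored).
#  - "germline" is a pseudo-record for the rachis + germ cells + stored
#    sperm; the nuclei count is an approximate literature point value
#    (germ nuclei ~1000 per adult plus ~300 stored sperm; reported ranges
#    vary with age and scoring).
cell,tissue,somatic,nuclei,ploidy_c
hyp7,hypodermis,TRUE,139,2
pm1,pharynx,TRUE,6,2
pm2,pharynx,TRUE,3,2
pm3,pharynx,TRUE,3,2
pm4,pharynx,TRUE,3,2
pm5,pharynx,TRUE,3,2
pm6,pharynx,TRUE,3,2
pm7,pharynx,TRUE,3,2
pm8,pharynx,TRUE,1,2
int1DL,intestine,TRUE,1,32
int1DR,intestine,TRUE,1,32
int1VL,intestine,TRUE,1,32
int1VR,intestine,TRUE,1,32
int2L,intestine,TRUE,1,32
int2R,intestine,TRUE,1,32
int3L,intestine,TRUE,1,32
int3R,intestine,TRUE,1,32
int4L,intestine,TRUE,1,32
int4R,intestine,TRUE,1,32
int5L,intestine,TRUE,1,32
int5R,intestine,TRUE,1,32
int6L,intestine,TRUE,1,32
int6R,intestine,TRUE,1,32
int7L,intestine,TRUE,1,32
int7R,intestine,TRUE,1,32
int8L,intestine,TRUE,1,32
int8R,intestine,TRUE,1,32
int9L,intestine,TRUE,1,32
int9R,intestine,TRUE,1,32
cuticle,cuticle,TRUE,0,2
germline,germline,FALSE,1300,2
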