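# VEGF signaling pathway members (KEGG map04370), keyed by the gene
# titles used in the worked example plus standard symbols.
vascular endothelial growth factor
SPHK1 (sphingosine kinase type 1) interacting protein (Hs.) (DBSS)
neuroblastoma RAS viral (v-ras) oncogene homolog
v-raf-1 murine leukemia viral oncogene homolog 1
nuclear factor of activated T-cells, cytoplasmic, calcineurin-dependent 4
ras-related C3 botulinum toxin substrate 1
nitric oxide synthase (DBSS)
VEGFA
SPHKAP
NRAS
RAF1
NFATC4
RAC1
NOS3
KDR
FLT1
PIK3CA
AKT1
PLCG1
PRKCA
MAPK1
MAPK3
MAPK14
HRAS
KRAS
SRC
PTK2
PXN
CDC42
PPP3CA
PLA2G4A
PTGS2
SH2D2A
SHC2
HSPB1
MAPKAPK2
MAPKAPK3
BAD
CASP9
NOS2
RAC2
RAC3
SPHK1
SPHK2
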