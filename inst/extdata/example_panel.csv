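"gene","category"
"THY1","fibroblast"
"COL1A1","fibroblast"
"COL5A2","fibroblast"
"FN1","fibroblast"
"VIM","fibroblast"
"SNAI2","fibroblast"
"TWIST1","fibroblast"
"PRRX1","fibroblast"
"S100A4","fibroblast"
"DCN","fibroblast"
"POU5F1","pluripotency"
"SOX2","pluripotency"
"NANOG","pluripotency"
"LIN28A","pluripotency"
"ZFP42","pluripotency"
"DPPA4","pluripotency"
"DNMT3B","pluripotency"
"TDGF1","pluripotency"
"SALL4","pluripotency"
"FOXD3","pluripotency"
"GDF3","pluripotency"
"UTF1","pluripotency"
"TERT","pluripotency"
"ZIC3","pluripotency"
"OTX2","pluripotency"
"STAT3","pluripotency"
"KLF4","pluripotency"
"MYC","pluripotency"
"FGF4","pluripotency"
"LEFTY2","pluripotency"
"NODAL","pluripotency"
"NR0B1","pluripotency"
"REST","pluripotency"
"CDH1","intermediate"
"EPCAM","intermediate"
"ALPL","intermediate"
"KRT8","intermediate"
"KRT18","intermediate"
"CLDN6","intermediate"
"EZH2","chromatin"
"SUZ12","chromatin"
"EED","chromatin"
"JARID2","chromatin"
"DNMT3A","chromatin"
"SETDB1","chromatin"
"KDM5B","chromatin"
"HELLS","chromatin"
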