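# Default synthetic study: 170 cells spanning MRC-5 fibroblast -> H9 hESC
# with a productive continuum and an alternate branch, on the packaged
# 48-assay panel (genes: default).
genes: default
nFib: 20
nIntermediate: 92
nAlt: 38
nPluri: 20
gapdhCtMean: 18
gapdhCtSd: 1.2
qcFailFraction: 0.05
seed: 1
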