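# scReprogram

Single-cell transcript dynamics of OSKM reprogramming to pluripotency.

Human fibroblasts transduced with OCT4/SOX2/KLF4/c-MYC spend most of
their conversion to iPSC in a "stochastic phase" of apparently random
pluripotency-gene expression. `scReprogram` implements a single-cell
RT-qPCR analysis showing that this phase is an *ordered probabilistic*
process: it places each cell on a reprogramming progression axis
computed from binarized detection profiles, models per-gene
detection-frequency dynamics along that axis, and tests whether
gene–gene co-expression exceeds what the shared axis alone would
produce. The package is aimed at groups profiling reprogramming (or
comparable state transitions) with targeted single-cell qPCR panels,
and at method developers who want a fully synthetic, ground-truthed
test bed for trajectory-conditioned models of binary detection data.

## The model

For a cell with binary detection profile, similarity to an anchor group
*G* (fibroblast MRC-5 or hESC H9) is

    sim_G = (d_FP - d_cell,G) / (d_FP - d_G,G)

with `d_FP` the mean anchor separation and `d_G,G` the anchor's internal
dispersion; the progression estimate is
`(sim_PLURI + (1 - sim_FIB)) / 2` and the off-trajectory distance is
`|sim_FIB + sim_PLURI - 1| / sqrt(2)`. Along the axis, each gene's
detection frequency is fit by

* a **uniform null** — a line anchored at the observed endpoint
  frequencies (random gradual change), and
* **Gaussian cumulative models** —
  `f(x) = b + Σ a_i Φ((x - μ_i)/σ_i)` with one or two components
  (activation/inactivation biased toward a specific point; two
  components capture transient genes),

compared by small-sample AICc (`n_eff ln MSE + 2k + 2k(k+1)/(n_eff-k-1)`)
and a bootstrap lack-of-fit F-test. Co-expression is assessed as the
observed pairwise Pearson correlation of detection indicators minus its
mean under simulated populations in which every gene is drawn
independently from its fitted curve, with Monte-Carlo-calibrated
Fisher-z significance. A synthetic-data generator with known latent
progression, gene-specific curves, an alternate branch and injectable
co-regulated modules underpins all validation. The methods vignette
(`vignettes/reprogramming-dynamics.Rmd`) documents every numerical
choice.

## Worked example

```r
library(scReprogram)

sim <- simulateReprogramming(simConfig(seed = 7))   # 170-cell study
qc  <- qcFilter(sim$experiment)                     # GAPDH Ct >= 25 out
rs  <- computeTrajectory(normalizeToGapdh(qc$experiment))
rs  <- somPartition(rs)
rs
#> class: ReprogramSet
#> dim: 48 169
#> assays(3): ct detected level
#> ...
#> normalizer: GAPDH
#> categories: chromatin(8) fibroblast(10) intermediate(6) normalizer(1) pluripotency(23)
#> trajectory: progression in [-0.06, 1.09], 17 outlier(s)

truth <- sim$truth$cells
idx <- match(colnames(rs), truth$cell_id)
prod <- truth$branch[idx] == "productive"
cor(colData(rs)$progression[prod], truth$progression[idx][prod],
    method = "spearman")
#> [1] 0.9709514

analyzed <- !colData(rs)$outlier & colData(rs)$som_group != "Alt"
fits <- fitActivationModels(rs, cells = analyzed)
fits$models[["NANOG"]]$selection$model
#> ActivationModel (gauss1) for NANOG: k=4, mse=0.0164, AICc=-38.07
#>   baseline 0.103; components: a=0.90 mu=0.899 sigma=0.034
```

One QC failure was injected and removed (169 of 170 cells retained);
the computed progression tracks the latent progression of
productive-branch cells (Spearman 0.97 here; ≥ 0.9 is the validated
bound), the 10% off-trajectory rule flags 17 cells, and the sharp
pluripotency gene NANOG is recovered as a tight one-component
activation late on the axis — at μ = 0.90 in *computed-axis* units,
where the latent midpoint 0.75 lands after the axis compresses near the
hESC anchor (see the vignette's limitations). `runPipeline(pipelineConfig())`
executes the same stages end to end and writes per-stage CSVs plus a
JSON manifest; `correlationAnalysis(rs, fits, cells = analyzed)` adds
the background-corrected co-expression calls.

Real instrument exports load with `loadCtTable()` (wide CSV, cells ×
genes, `cell_id`/`group`/`day`/`facs` annotations, Ct 40 = undetected);
an XLSX table can be converted with
`readxl::read_excel()` + `write.csv()` first.

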