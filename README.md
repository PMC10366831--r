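# vctdbt — virtual clinical trials for DBT segmentation

`vctdbt` is an R toolkit for simulation-based (virtual clinical trial)
studies of digital breast tomosynthesis (DBT) segmentation. It is aimed at
imaging researchers who want to ask, without scanning a single patient:
*how do the acquisition geometry and the training loss of a neural
segmenter affect the recovery of the 3D breast outline ("convex hull") and
of adipose/dense tissue from DBT reconstructions?*

The package simulates the whole chain:

1. **Phantoms** — voxelized compressed breasts (air / adipose / dense) with
   a curved outline between flat paddle- and support-contact bands,
   sampled from a screening-population distribution (CBT median 60.50 mm,
   IQR 51.50–69.5; %VBD median 12.75, IQR 8.40–20.00; CBT capped at
   85 mm); dense tissue placed by seeded octree subdivision to a target
   density within ±0.5 points.
2. **Acquisition** — three scanning geometries as explicit source
   trajectories: conventional (15 projections, linear left–right, ±7.5°),
   T (8 LR + 7 posteroanterior projections, ±7.5°), and extra-wide-range
   XWR (91 projections on a 738 mm arc, ±45°, 6× total exposure). Cone-beam
   line integrals by exact Siddon ray tracing; optional Poisson noise.
3. **Reconstruction** — unfiltered voxel-driven simple backprojection (the
   algorithm that exposes the convex-hull artifact), plus a z point-spread
   FWHM quantifier of the out-of-plane artifact.
4. **Segmentation** — a compact 3D U-Net (native R, BLAS convolutions,
   hand-derived gradients, Adam at lr 0.01, batch 2, checkpoints every
   5 epochs) trained with the focal Tversky loss

   `TI_c = (Σ p_ic g_ic + ε) / (Σ p_ic g_ic + α Σ p̄_ic g_ic + β Σ p_ic ḡ_ic + ε)`,
   `FTL = Σ_c (1 − TI_c)^γ`, α = 0.7, β = 0.3, γ = 3/4,

   either alone (tissue task) or combined with a second FTL on merged
   binary air/tissue maps (outline task).
5. **Evaluation** — slice-wise confusion counts as a function of the signed
   distance `d` to the central slice, pooled into 10 equal-count distance
   bins; Jaccard, Dice, precision, recall, accuracy, Jaccard distance;
   Kruskal–Wallis and Wilcoxon–Mann–Whitney model comparisons; accuracy
   colormaps; improvement statistics `100·(JD_ref − JD_new)/JD_ref`.

The four canonical models are `I1` (conventional, tissue loss only),
`I1and2` (conventional, combined loss), `II1and2` (T, combined), and
`III1and2` (XWR, combined).

## A worked example

```r
library(vctdbt)

cfg <- experiment_config(out_dir = "runs/demo", master_seed = 1)
report <- run_vct(cfg)   # ~5 minutes on one CPU at the desk-scale defaults

air <- subset(report$bin_table, class == "air")
round(tapply(air$jaccard_distance_mean, air$model, mean), 4)
#>       I1   I1and2  II1and2 III1and2
#>   0.0341   0.0314   0.0194   0.0355

improvement(0.0341, 0.0194)
#> [1] 43.10850
```

The first table is the mean air Jaccard distance (the fraction of the
air/breast union misassigned — lower is better) per model, averaged over
the ten distance bins: the combined loss improves on the tissue-only loss
(`I1and2` vs `I1`), and the T geometry gives by far the best
breast-outline recovery — the `improvement()` line expresses the T-scan
effect as "about 43% of the conventional scan's air misclassification
resolved" in this replicate. Exact values vary with the master seed; the
directional orderings are the robust finding (see the methods vignette
for which full-scale findings do and do not carry to desk scale). `runs/demo/` holds the phantoms (NIfTI + CSV manifest),
per-geometry reconstructions, model weights and training histories, binned
records, and `table3.csv`–`table5.csv` summaries.

A thin command-line wrapper is installed with the package
(`system.file("cli", "vctdbt.R", package = "vctdbt")`) with subcommands
`geom`, `recon`, and `run`.

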