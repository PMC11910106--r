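# mitopink

Quantitative analysis of PINK1 transmembrane-variant phenotypes: confocal
mitochondrial-enrichment quantification, skeleton-based mitochondrial
network morphology, internally quenched (IQ) fluorogenic protease
kinetics, and transmembrane helix tilt analysis — each paired with a
synthetic-data generator that carries full ground truth, so every pipeline
can be validated end to end without access to the original microscopes,
plate readers, or trajectories.

PINK1 is a mitochondrial quality-control kinase whose TM helix is cleaved
by the rhomboid protease PARL; disease-linked substitutions in that helix
(C92F, R98W, I111S) change where the protein accumulates and how
efficiently it is cleaved. The package is aimed at cell biologists and
enzymologists who want these measurements as reproducible, scriptable
pipelines rather than interactive tool chains.

## What it computes

* **Enrichment ratio** per transfected cell:
  `R = mean(I_reporter | mito mask) / mean(I_reporter | cell \ mito mask)`,
  with masks from Otsu segmentation of a membrane-probe channel (cell) and
  a TOM20 channel (mitochondria) after wide-Gaussian (σ = 10 px)
  background correction, plus automated QC. `R ≈ 1` means an evenly
  distributed reporter; `R ≈ 3` strong mitochondrial retention.
* **Network morphology** (MiNA-style): one-pixel skeleton via iterative
  thinning, branch graph with endpoints/junctions, mean and summed branch
  length (µm), footprint (µm²), individuals vs networks.
* **Michaelis–Menten kinetics** from progress curves: blank subtraction,
  proteinase-K full-digest calibration (RFU → µM), bounded-conversion
  initial velocities, nonlinear fit of `v = Vmax·S/(Km+S)`,
  `kcat = Vmax/[E]`, catalytic efficiency `kcat/Km`, and variant/WT
  efficiency ratios with replicate-level paired tests.
* **Helix tilt**: `θ = arccos|â·n̂|` between the principal axis of a
  residue span (Cα points) and the membrane normal, folded to [0°, 90°];
  span presets for the TM helix (89–118), the soluble helix (119–135) and
  the AlphaFold TM boundaries (92–118).
* **Group statistics**: Brown–Forsythe unequal-variance one-way ANOVA
  (F* with Satterthwaite df), Šidák adjustment `1−(1−p)^m`, paired *t*
  tests, densitometry normalisation to a reference condition.

## Worked example

Generate five synthetic cells with an R98W-like phenotype (2.98-fold
mitochondrial enrichment, fragmented network), quantify them, and compute
morphology for the first cell:

```r
library(mitopink)

batch <- generateBatch(sceneConfig(enrichment = 2.98,
                                   mitoMode = "fragmented"),
                       n = 5, seed = 11)
df <- quantifyBatch(batch)
df[, c("scene_id", "ratio", "mito_area", "qc_pass")]
#>           scene_id ratio mito_area qc_pass
#> 1 scene_seed191838 2.988     71.07    TRUE
#> 2 scene_seed296567 3.048     71.54    TRUE
#> 3 scene_seed401296 3.014     69.88    TRUE
#> 4 scene_seed506025 3.031     70.92    TRUE
#> 5 scene_seed610754 3.108     71.06    TRUE
attr(df, "summary")
#>   n n_pass mean_ratio median_ratio sd_ratio
#> 1 5      5      3.038        3.031  0.04488
```

The mean recovered ratio (3.04) sits within 2% of the generating value
2.98; `qc_pass` would flag any cell whose segmentation failed the area or
border rules. Morphology of the first cell's true mask:

```r
morphologyStats(mitoMask(batch[[1]]$truth), pixelSize(batch[[1]]$scene))
#>   mean_branch_length summed_branch_length footprint n_branches ...
#> 1              0.908                  135      77.1        149 ...
```

A full kinetics experiment under the 30-fold efficiency-gap preset
(duplicate wells × 3 replicates, 3-min sampling over 2.5 h, substrate
0.1–100 µM, enzyme 0.8 µM, 5% velocity noise):

```r
kin <- runKineticsExperiment(seed = 1)
kin$summary
#>   condition kcat_mean kcat_sem Km_mean Km_sem efficiency_mean efficiency_sem
#> 1        wt    0.0204 0.000741   61.30   3.83        0.000334       9.47e-06
#> 2   variant    0.0507 0.001088    5.49   0.50        0.009344       6.15e-04
kin$efficiencyRatio
#> [1] 27.94
```

The recovered efficiency ratio (27.9) is within 7% of the generating
30-fold gap; `kin$pairedT` holds the replicate-level paired test on log
efficiencies.

Helix tilt on a synthetic trajectory:

```r
frames <- synthHelixTrajectory(tilt = 25, nFrames = 200, noiseSigma = 0.3,
                               seed = 2)
tiltSummary(tiltSeries(frames, spanPresets()$tm))$mean
#> [1] 25.06
```

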