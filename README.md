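# bccmorph

Morphometry and segmentation evaluation for **nodular (N)** vs
**micronodular (MN)** basal cell carcinoma histology.

BCC grows as basaloid islands in a fibromyxoid stroma; around each island
four components can be annotated per pixel: tumor core (**T**), the
palisaded rim where the island touches stroma (**TT**), the peritumoral
cleft (**PC**) and the stroma itself (**S**). The low-risk N subtype has
few large islands; the high-risk MN subtype many islands under 0.15 mm.
`bccmorph` quantifies how the two subtypes differ per component along two
independent routes:

1. **Trimmed-GLCM morphometry.** Per component image: a horizontal
   gray-level co-occurrence matrix (offset (0,1), 9 levels on [0,255],
   background row/column trimmed to 8x8), the 14 Haralick texture
   features, and unstandardized central histogram moments
   `m_k = (1/n) Σ (x_i − m)^k`, k = 2..4. Per component and feature, a
   two-sided pooled t-test compares subtypes; the headline statistic is
   the count of significantly different Haralick features per component
   (0–14).
2. **Segmentation evaluation.** Eight pixel classes (component x
   subtype); per-class one-vs-rest accuracy, IoU = TP/(TP+FP+FN),
   precision, recall and F1 from pooled confusion matrices; a repeated
   70/15/15 resampling protocol with mean/SD and unweighted macro
   averages; best-run selection by macro IoU; uniform-patch mining; tiled
   whole-image inference. The deep network of the original study is out
   of scope — a pluggable pixel-classifier contract with a desk-scale LDA
   baseline stands in, and external label maps can be imported.

Because the underlying clinical images are not deposited, the package
ships a seeded synthetic generator with exact ground-truth masks that
encodes the statistical structure the analysis assumes (island geometry
per subtype, divergent cleft texture, near-identical rim texture, weakly
divergent stroma), so the whole pipeline runs and is tested end to end.

## Worked example

```r
library(bccmorph)

# a desk-scale two-subtype dataset: 30 N + 30 MN images of 512x384 px
spec <- synthetic_spec(preset = "desk", n_nodular = 30,
                       n_micronodular = 30, seed = 42)
ds   <- generate_dataset(spec)

# morphometry: feature table and per-component significance counts
ft  <- build_feature_table(ds)
rep <- significance_report(ft, alpha = 0.05)
print(rep)
#> Significantly different Haralick features per component (alpha = 0.05 ):
#>   T   13 / 14
#>   TT   0 / 14
#>   PC  14 / 14
#>   S    9 / 14
```

The counts mirror the qualitative clinical finding: the peritumoral
cleft is the most subtype-divergent component and the palisade rim the
least, with core and stroma in between.

```r
# segmentation evaluation with the LDA baseline, 3 resampling runs
prot <- run_protocol(ds, runs = 3, seed = 7)
print(prot$report)
#> <run_report> 3 run(s); macro means:
#>  accuracy       iou precision    recall        f1
#>      0.99      0.75      0.83      0.84      0.83
nm <- cm_normalized(prot$best_confusion)
round(nm[c("TT-N", "TT-MN"), c("T-N", "TT-N", "T-MN", "TT-MN")], 2)
#>        predicted
#> target   T-N TT-N T-MN TT-MN
#>   TT-N  0.27 0.52 0.01  0.17
#>   TT-MN 0.01 0.17 0.33  0.46
signif(cross_subtype_confusion(prot$best_confusion), 2)
#>       T      TT      PC       S
#> 9.6e-05 1.7e-01 1.8e-02 0.0e+00
```

Per-class IoU/F1/etc. for each run are in `prot$report$per_run`; the
macro row is the unweighted mean over the eight classes. The palisade
rim is the hardest class — it is confused with its neighboring core far
more than across subtypes — while stroma is essentially never confused
across subtypes; the same confusion structure reported for the original
network.

The full pipeline (generate -> features -> stats -> segeval -> report
bundle with table analogs and a uniform-patch gallery):

```r
cfg <- pipeline_config(dataset = list(preset = "desk", n_nodular = 12,
                                      n_micronodular = 12),
                       runs = 3, seed = 42, out_dir = "out")
bundle <- run_experiment(cfg)
```

or from the shell: `exec/bccmorph all --out out --seed 42`.

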