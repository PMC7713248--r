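# thyrotherm

Can a malignant thyroid nodule be detected from outside the neck as a
skin-temperature anomaly? `thyrotherm` implements the two computational
studies behind that question as one tested R package:

1. **Bioheat simulation.** A steady-state Pennes solver on a layered 2-D
   neck cross-section (skin / fat / muscle / thyroid gland / elliptic
   nodule, insulated trachea), quantifying how nodule size and subcutaneous
   fat thickness shape the skin-surface temperature. The model is

   ρc ∂T/∂t = k ∇²T + w_b ρ_b c_b (T_b − T) + Q_met,

   solved with a finite-volume scheme on a polar grid (grid-aligned layer
   interfaces and skin arc, sparse Cholesky), verified against a
   closed-form 1-D multilayer solution.

2. **Thermogram screening.** The asymmetry-parameter pipeline for 640×480
   temperature matrices: grey-level ROI mapping, geometric-centre mirror
   axis, P_A(x, y) = M(x, y) − M(2o_x − x, y), thresholding at l (default
   0.3 °C), morphological opening, 8-connected candidate extraction,
   224×224×3 crop normalisation, class-specific augmentation with exact
   2^n count bookkeeping, a synthetic-thermogram generator with ground
   truth, and a classifier evaluation harness (confusion matrix,
   precision/recall, ROC/PR AUCs).

The published tissue table's perfusion units are ambiguous; the package
makes the interpretation explicit (`tissue_properties("literal")`,
`"per_min"`, `"calibrated"`) and documents which reading reproduces the
reported temperature field — see the methods vignette
(`vignettes/thyroid-thermal-screening.Rmd`).

## Worked example

Solve the reference configuration (fat 1.2 cm, 1.0×1.57 cm nodule) and
screen a synthetic thermogram:

```r
library(thyrotherm)

g   <- build_neck_section(1.2, nodule_spec(1.0, 1.57))
fld <- solve_steady(pennes_problem(g, tissue_properties("calibrated")),
                    resolution = 0.025)
ctr <- g$nodule$center
sample_field(fld, ctr[1], ctr[2])    # 37.87  nodule centre, degC
sample_field(fld, -ctr[1], ctr[2])   # 37.03  contralateral lobe
prof <- line_profile(fld)            # radial line through the nodule
layer_drop(prof, g, "muscle")        # 0.54   degC across the muscle layer
layer_drop(prof, g, "fat")           # 1.60   degC across the fat layer
skin_arc_length(g)                   # 19.70  cm of skin arc

sy  <- synth_thermogram(synth_config(delta_t = 1.0, sigma = 0.04, seed = 3))
det <- detect_candidates(sy$tg, sy$roi_mask, l = 0.3)
length(det$regions)                                    # 1 candidate
mask_iou(det$regions[[1]]$mask, sy$regions[[1]]$mask)  # 0.99 vs ground truth

aug <- augment(replicate(16, matrix(runif(64), 8), simplify = FALSE),
               augmentation_plan("nodular"))
length(aug)                          # 256: 16 crops x 2^4 operations
```

The numbers mean: the tumour's metabolic heat lifts the nodule ~0.85 °C
above the contralateral lobe, but the fat layer absorbs most of the
gradient on the way out (1.60 °C across 1.2 cm of fat vs 0.54 °C across
1.0 cm of muscle), which is why detectability collapses for thick
subcutaneous fat — the central finding both studies share. On the synthetic
thermogram, a 1 °C lesion against 0.04 °C sensor noise is recovered
essentially exactly.

The `analysis/` directory holds the full workflow as numbered scripts:

```sh
Rscript analysis/01_simulate_reference.R   # reference fields, both perfusion readings
Rscript analysis/02_size_fat_sweep.R       # 4 sizes x 3 fat thicknesses
Rscript analysis/03_screening_demo.R       # synthetic screening end to end
Rscript analysis/04_train_eval.R           # 16/68 -> 256/272/528 -> metrics
```

Each writes its tables under `results/`.

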