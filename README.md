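# strokeseg

Desk-scale ischemic stroke lesion segmentation on multimodal brain MRI,
in R. The package implements an end-to-end pipeline of the kind used in
clinical stroke imaging studies — for researchers who want a fully
inspectable, CPU-scale, reproducible implementation of every stage rather
than a GPU black box:

* a **synthetic multimodal phantom generator** (T1 / T2 / FLAIR / DWI +
  TTP perfusion channels, ellipsoidal lesions, known ground truth);
* an **encoder–decoder segmentation network** (U-Net style) with a
  centered crop layer on the skip connections and a dual-weighted
  auxiliary softmax head (loss = 0.8 · main + 0.2 · auxiliary
  cross-entropy), trained with Adam (lr 0.0001, momentum 0.9, L2
  regularization 0.0005, zero bias initialization) — forward and backward
  passes written out against small Rcpp kernels;
* **fully connected CRF refinement** by exact mean-field inference with
  Potts compatibility and the two-kernel Gaussian binary potential
  ω₁·exp(−|pᵢ−pⱼ|²/2σ²_α − |Iᵢ−Iⱼ|²/2σ²_β) + ω₂·exp(−|pᵢ−pⱼ|²/2σ²_γ),
  validated against exhaustive enumeration on small instances;
* **3-D connected-component postprocessing**: a mean-TTP screen
  (threshold 100 gray values) and a relative-volume screen (threshold 0.1
  of the largest component);
* an **evaluation suite**: Dice, precision, recall, Hausdorff distance
  and average symmetric surface distance (in mm, spacing-aware);
* deterministic **CSVD burden scoring** (0–4: one point each for
  qualifying WMH, microbleeds, perivascular spaces, lacunae) and the
  **MoCA < 26** cognitive-impairment cut-off.

All volumes are NIfTI (`.nii` / `.nii.gz`); tabular results come back as
tibbles.

## Worked example

Generate a phantom, train a small network, refine, postprocess, evaluate:

```r
library(strokeseg)

cfg    <- phantom_config(shape = c(64, 64, 1), seed = 99)
sample <- generate_phantom(cfg)           # held-out case
ds     <- generate_dataset(cfg, 40, seed = 5)

model <- build_model(list(channels = c("T1", "T2", "FLAIR", "DWI"),
                          depth = 2, base_channels = 8, seed = 1))
model <- train_network(model, ds,
                       train_config(max_iterations = 300, seed = 2))

pr    <- predict(model, sample$stack)                       # coarse mask
ref   <- mean_field_refine(pr$probs, sample$stack$T1)       # dense CRF
final <- postprocess(ref$map, sample$stack$TTP)             # TTP + volume

evaluate(final, sample$truth)
#> # A tibble: 1 × 9
#>    dice precision recall hd_mm assd_mm    tp    fp    fn    tn
#>   <dbl>     <dbl>  <dbl> <dbl>   <dbl> <int> <int> <int> <int>
#> 1     1         1      1     0       0   281     0     0  3815
```

The 281-voxel lesion is recovered exactly: Dice, precision and recall are
1 and both surface distances are 0 mm. On noisier or smaller-training
runs these drop below 1 — `run_pipeline()` automates the whole study over
many held-out phantoms and reports per-sample and mean metrics:

```r
man <- run_pipeline(validate_config(list(seed = 1,
                                         train = list(max_iterations = 450))))
man$summary
```

An empty configuration resolves to the reference defaults (learning rate
0.0001, momentum 0.9, regularization 0.0005, 21,000 max iterations, loss
weights 0.8/0.2, TTP threshold 100, volume-ratio threshold 0.1). A thin
command-line front end with subcommands (`phantom-generate`, `train`,
`predict`, `refine`, `postprocess`, `evaluate`, `csvd-score`, `run-all`)
ships in `inst/cli/strokeseg`.

Clinical scoring is data-frame-first:

```r
csvd_score(data.frame(pvwmh_fazekas = 0, dwmh_fazekas = 3,
                      cmb_count = 2, pvs_grade = 3, lacuna_count = 1))
#> ... wmh_point 1, cmb_point 1, pvs_point 1, lacuna_point 1, csvd_total 4
classify_cognition(c(25, 26))
#> [1] impaired     not_impaired
```

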