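# pemt — perturbation-enhanced mean-teacher segmentation

Semi-supervised semantic segmentation of 2D images for settings where
pixel-wise labels are scarce (the motivating case: cardiac MRI, where a
few labeled scans sit next to many unlabeled ones). A **student**
network is trained by SGD; a **teacher** tracks it through an
exponential moving average of the weights and supervises the student on
*unlabeled* images through a consistency penalty. On top of the classic
uncertainty-aware mean teacher the package implements two refinements:

* **pEMA** — after each teacher update the student receives an adaptive
  weight perturbation `θ ← θ + β·mod(θ*, θ)` built from the element-wise
  (floored) modulus of teacher vs student weights, which breaks the
  tight coupling plain EMA induces between the two models;
* **RUM** — a residual-guided uncertainty map
  `RUM_υ = Σ_c p̄_c (1 − p̄_c)^{υ − p̄_c}` computed from the mean softmax
  over `K` Monte-Carlo dropout passes of the teacher, used to exclude
  unreliable (high-uncertainty) pixels from the consistency loss via a
  ramped threshold τ(t).

The total objective is `L = L_sup + λ(t)·L_cons` with
`L_sup = CE + soft-Dice` on labeled images,
`λ(t) = 0.1·e^{−5(1−t/t_max)²}`, and `L_cons` the uncertainty-masked
pixel-wise MSE between student and teacher probabilities. Evaluation
uses DSC, Jaccard, 95th-percentile Hausdorff and average surface
distance.

Everything is self-contained: a compact 2D U-Net backbone with
hand-written backprop (compiled convolution kernels, < 1e5 parameters,
trains in minutes on one CPU), a seeded synthetic generator of
cardiac-like images with fuzzy noisy boundaries, the five-way variant
switchboard (`supervised`, `mt`, `uamt`, `uamt_rum`, `pemt`), and a
NIfTI import path for real volumes.

## Worked example

```r
library(pemt)

spec <- dataset_spec(n_total = 40, labeled_fraction = 0.1,
                     image_size = 32, n_val = 8, seed = 1)
ds   <- generate_dataset(spec)          # 4 labeled, 36 unlabeled, 8 val
cfg  <- train_config(variant = "pemt", t_max = 150,
                     batch_labeled = 4, batch_unlabeled = 4, seed = 1)
fit  <- fit_pemt(ds, cfg)

tail(fit$log[, c("t", "lambda", "tau", "supervised", "masked_fraction")], 3)
#> # A tibble: 3 × 5
#>       t lambda   tau supervised masked_fraction
#>   <dbl>  <dbl> <dbl>      <dbl>           <dbl>
#> 1   148 0.0999 0.348      0.282           0.978
#> 2   149 0.1000 0.351      0.455           0.974
#> 3   150 0.1    0.354      0.373           1

ev <- evaluate_fit(fit, ds$validation)
round(colMeans(ev[, c("dsc", "jac", "hd95", "asd")], na.rm = TRUE), 3)
#>   dsc   jac  hd95   asd
#> 0.787 0.654 1.958 0.706
```

By iteration 150 the consistency weight λ has ramped to its plateau 0.1
and the threshold τ to the RUM maximum (≈ 0.354 at υ = 2), so nearly all
pixels participate in the consistency loss (`masked_fraction ≈ 1`);
early in the run the mask drops the uncertain boundary pixels. The
validation block reports mean Dice/Jaccard overlap and surface distances
(pixels) of the student's predictions; with only 4 labeled images the
semi-supervised run recovers a mean DSC around 0.79 on this task.

A command-line front end mirroring the R API lives at
`inst/scripts/pemt` (`pemt train|evaluate|ablate --config run.yaml`);
`ablate()` sweeps the RUM shape υ and the pEMA strength β
one-factor-at-a-time and returns the familiar ablation table.

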