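# tagloc3d

Three-dimensional localization of RFID-tagged animals from received signal
strength (RSSI) reader logs.

Passive UHF RFID is one of the few ways to track small or aquatic animals
that cannot carry batteries: antennas over the habitat power and read a
tail-mounted tag, and each detection reports an RSSI per antenna. This
package implements a complete localization chain for such deployments —
motivated by monitoring Chinese giant salamanders under four antennas
suspended over breeding ponds — together with the simulation and
evaluation machinery needed to develop and verify it without field
hardware.

## What it implements

* **Log-distance path-loss model and calibration.**
  $PL(d) = A - 10\,n\,\log_{10}(d/d_0) - N_0$, with `calibrate_A()` (mean
  RSSI at 1 m) and `calibrate_n()` (mean per-pair exponent
  $(A - RSSI_i)/(10\log_{10} d_i)$), plus the inverse map
  `rssi_to_distance()`.
* **RSSI filtering** — `trim_extremes()`, the asymmetric band filter
  `sigma_filter()` (keep $(u - 0.5\sigma,\ u+\sigma)$; obstruction only
  weakens signals, so low readings are less trusted), the zero-score
  correction `correlation_correct()` ($\partial = \tfrac23 E_m$), and
  `build_fingerprint()`.
* **3D LANDMARC** — `estimate_position()`: weighted k-nearest-neighbour
  centroid in RSSI space over a reference-tag grid.
* **GAIN imputation** — `train_gain()` / `gain_impute()`: a generative
  adversarial imputation network with mask, random-matrix and hint
  machinery ($\hat X = M \odot X + (1-M) \odot \bar X$), optionally
  conditioned on location and path-loss-model outputs.
* **Dual-stream transformer locator (D-Tr)** — `build_locator()` /
  `train_locator()`: parallel transformer encoders over the raw RSSI
  window and its first difference, fused into a 3D coordinate regression;
  `build_baseline()` provides matched-budget single-stream, GRU, LSTM and
  TCN comparators. All networks are implemented in-package (base matrix
  ops + small C++ kernels) with finite-difference-verified backprop.
* **RF scene simulator** — `scene_config()` / `simulate_log()` /
  `make_training_set()`: path-loss RSSI with iid or AR(1) shadow fading,
  reference grids, random-walk trajectories, Bernoulli dropout and
  occlusion boxes.
* **Evaluation statistics** — `euclidean_errors()`, `summarize_errors()`,
  `per_axis_relative_error()`, `pct_reduction()`, `paired_t_test()` (with
  Cohen's d effect sizes).

The package ships the deployment's printed measurement tables
(`tagloc_calib_1m()`, `tagloc_calib_pairs()`, `tagloc_benchmark_positions()`,
`tagloc_ablation_summary()`) as plain-CSV example data.

## Worked example

```r
library(tagloc3d)

# 1. Calibrate the propagation model from the bundled field tables
A <- calibrate_A(tagloc_calib_1m()$rssi_dbm)       # -54.41667 -> -54.42 dBm
pairs <- tagloc_calib_pairs()
ok <- !is.na(pairs$rssi_dbm)
n <- calibrate_n(round(A, 2), pairs$rssi_dbm[ok], pairs$distance_m[ok])
round(c(A = A, n = n), 3)
#>       A       n
#> -54.417   1.218

model <- path_loss_model(round(A, 2), round(n, 3))
rssi_to_distance(model, -62.17)                    # 4.33 m for a -62.17 dBm read
#> [1] 4.328017

# 2. Simulate a scene and localize with the LANDMARC baseline
cfg  <- scene_config()
sim  <- simulate_log(cfg, n_steps = 200, seed = 7)
fp   <- build_fingerprint(sim$log, window_size = 10)
refs <- make_reference_fingerprints(cfg, seed = 8)
target <- vapply(sort(unique(fp$antenna_id)),
                 function(a) fp$rssi_dbm[fp$antenna_id == a & fp$window_index == 1],
                 numeric(1))
estimate_position(target, refs, knn_config(k = 4))
#>           x           y           z
#>  0.02981095 -0.41577396  0.94276602   # meters
#> attr(,"neighbors")
#> [1] 116 124  67 115
#> attr(,"weights")
#> [1] 0.6082498 0.1684521 0.1144680 0.1088302

# 3. Evaluate predictions
bp <- tagloc_benchmark_positions()
truth <- as.matrix(bp[bp$model == "truth", c("x", "y", "z")])
dtr   <- as.matrix(bp[bp$model == "dtr",   c("x", "y", "z")])
per_axis_relative_error(truth, dtr)
#>        x        y        z
#> 6.117216 3.311264 2.142857            # percent per axis
```

The numbers above are what the code prints: the calibrated reference power
(−54.42 dBm at 2 decimals), the path-loss exponent (1.218), the implied
distance of a −62.17 dBm reading (≈4.33 m), a LANDMARC estimate inside
the arena, and the per-axis relative errors of the bundled dual-stream
benchmark column (6.118 %, 3.311 %, 2.143 %).

Training the locator end to end on the synthetic benchmark:

```r
sc  <- make_benchmark_scene(seed = 1)       # 2000 train / 500 test windows
m   <- build_locator(dtr_config("desk"), n_antennas = 4, seed = 1)
m   <- train_locator(m, sc$train, seed = 1)
err <- euclidean_errors(sc$test$target, predict_positions(m, sc$test))
summarize_errors(err)
```

See `vignettes/tagloc3d-methods.Rmd` for the models, assumptions, profile
definitions and known limitations, and `inst/cli/tagloc` for a thin
command-line wrapper (`simulate`, `calibrate`, `filter`, `locate`,
`evaluate`, `run`).

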