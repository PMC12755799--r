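# dicecast

**How much training data does a biomedical segmentation model need?**

`dicecast` answers that question empirically. It trains a
depth-parameterized family of residual U-Nets (2D images or 3D volumes)
on nested subsets of a training pool — a grid of *data ratios* × *model
depths* — records the resulting learning curves of segmentation metrics
(Dice, IoU, recall, precision), fits recurrent (LSTM) forecasters to the
observed prefix of each curve to predict its remainder, and turns either
the observed or the forecast curve into two actionable numbers:

* the **plateau ratio** — the point of diminishing returns, the smallest
  data fraction beyond which the (smoothed) Dice stays within a tolerance
  ε of its full-data value, and
* the **minimal data ratio** achieving a target Dice (or "unreachable").

The core quantity is the Dice similarity coefficient of binary masks,
DSC = 2·|A∩B| / (|A| + |B|), related to IoU by DSC = 2·IoU/(1+IoU). A
learning curve is DSC on a held-out test set as a function of the
training-data ratio r ∈ (0, 1] at fixed model depth d. Forecasters see
curve points as (r, log10 parameter count, DSC) triples and predict the
next DSC either from actual history only (*one-step*) or autoregressively
from their own predictions (*full-step*), in uni- or bi-directional
flavours, with an OLS line `dsc ~ r` as baseline.

Everything runs without external data: the package ships synthetic 2D
(RGB, one bright irregular blob over textured background) and 3D
(4-channel volumes with a compact lesion) segmentation tasks plus a
saturating-curve simulator with known closed form. The networks
themselves (GEMM-based 2D/3D convolutions, batch norm, Adam, the LSTM)
are implemented in the package with Rcpp/RcppArmadillo kernels.

## Worked example

Simulate a family of learning curves (four depths, the 2%-step 50-ratio
ladder), forecast the unseen half of each curve from its observed half,
and estimate data sufficiency:

```r
library(dicecast)

ladder <- ratio_ladder(0.02, 1, 0.02)          # 50 ratios: 2%, 4%, ..., 100%
curves <- simulate_learning_curves(curve_family_spec(), ladder,
                                   depths = 3:6, seed = 42)

fc <- fit_forecaster(curves, forecaster_spec("uni_full_step", seed = 42),
                     observed_fraction = 0.5)
cv6  <- curves[curves$depth == 6, ]
pred <- predict_full_step(fc, cv6[1:25, ], horizon = 25,
                          future_ratios = cv6$data_ratio[26:50])
round(tail(pred, 3), 3)
#> [1] 0.965 0.966 0.968
mae_stats(pred, cv6$dsc[26:50])                # forecast error on the tail
#>       mean        std
#> 0.02476243 0.01210084

report <- sufficiency_report(curves, target_dsc = 0.85, epsilon = 0.01)
report$estimates[, c("depth", "plateau_ratio", "minimal_ratio_for_target")]
#>   depth plateau_ratio minimal_ratio_for_target
#> 1     3          0.82                     0.60
#> 2     4          0.98                     0.46
#> 3     5          0.64                     0.38
#> 4     6          0.92                     0.32
report$summary
#> $target_reachable
#> [1] TRUE
#> $best_depth
#> [1] 6
#> $best_ratio
#> [1] 0.32
#> $source
#> [1] "observed"
```

Reading the output: the full-step forecaster, trained only on the first
half of each (noisy) curve, tracks the held-out tail to a mean absolute
error of ~0.02 Dice; the deepest model reaches the 0.85 target with 32%
of the data, while the depth-3 model needs 60%; and gains plateau around
80–95% of the pool depending on depth and noise.

The calibrated full-size family reproduces the documented
parameter-count scaling (~×4 per depth step):

```r
for (d in 3:6) cat(sprintf("depth %d: %5.1f M parameters\n",
                           d, unet_param_count(unet_spec(d)) / 1e6))
#> depth 3:   6.0 M parameters
#> depth 4:  25.6 M parameters
#> depth 5: 103.9 M parameters
#> depth 6: 417.2 M parameters
```

To train real (desk-scale) segmenters instead of simulating curves, run
the end-to-end pipeline — synthetic dataset → grid → training → curve
assembly → forecasting → sufficiency report, with per-stage caching:

```r
res <- run_pipeline(list(seed = 1, out_dir = "run1"))   # ~4 min on 1 core
res$report$estimates
```

A thin command-line interface wraps the same functions
(`inst/cli/dicecast`): subcommands `synth`, `grid`, `train-grid`,
`evaluate`, `forecast`, `eval-forecast`, `estimate`, `run-all`,
`describe`.

## Package layout

| Area | Functions |
| --- | --- |
| Protocol | `ratio_ladder`, `training_grid`, `partition_dataset`, `subset_indices` |
| Synthetic tasks | `synth_seg_2d`, `synth_seg_3d`, `simulate_learning_curves`, `write_dataset`/`read_dataset` |
| Segmenters | `unet_spec`, `build_unet`, `unet_forward`, `count_parameters`, `unet_param_count` |
| Training | `train_segmenter`, `evaluate_segmenter`, `run_grid`, `default_hyper` |
| Metrics | `confusion_counts`, `seg_dsc`/`seg_iou`/`seg_recall`/`seg_precision`, `mae_stats` |
| Forecasting | `forecaster_spec`, `fit_forecaster`, `predict_one_step`, `predict_full_step`, `evaluate_forecasters`, `forecast_evaluation_table` |
| Sufficiency | `estimate_plateau`, `minimal_data_for_target`, `sufficiency_report` |
| Orchestration | `run_pipeline`, `default_run_config`, `validate_run_config`, `cli_main` |

The methods vignette (`vignettes/methods.Rmd`) documents the model
family and its parameter-count calibration, the training protocol, the
forecaster design, the plateau criterion, and the known limitations.
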