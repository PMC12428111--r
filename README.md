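# segrankloss

Rank-based loss aggregation for multi-class semantic segmentation under
noisy pixel annotations.

## The problem

Expert-annotated segmentation data — burn wounds, ultrasound, MRI — has a
characteristic asymmetry: *image-level* labels (which classes are present)
are reliable, while *pixel-level* masks are imprecise near region
boundaries. A plain mean-loss (ERM) objective spends gradient budget
fitting mislabeled boundary pixels. `segrankloss` implements a
loss-aggregation envelope that exploits the asymmetry by ranking
individual losses at two levels:

* **Image level** — emphasise hard examples: instead of the mean over all
  $I$ per-image losses, use the mean of a rank window
  $\frac1k\sum_{i=i_0}^{i_0+k-1}\ell_{[i]}$ with $i_0 = I-k+1$ (average
  top-$k$), optionally shrinking $k$ from $I$ to $5\%I$ over training
  (`atk_dec`). Hard selection is smoothed by a boxcar of sigmoids
  $\zeta_\alpha(i,i_0,k)=S_\alpha(i,i_0)\,S_\alpha(-i,-(i_0+k))$, with
  $\alpha$ fixed at 20 (`sm`) or decreasing to 1 (`sm_inc`).
* **Pixel level** — discard likely-mislabeled pixels: the **"bottom all
  but σ"** filter retains only pixels whose loss is at most the
  within-image mean plus one standard deviation of the pixel losses.

The per-pixel loss is the combination
$\ell_j = \lambda_{CE}\,\ell_{CE} + \lambda_{DC}\,(1 - f\,\rho_j)$ of
cross-entropy with the per-pixel term of the *continuous Dice
coefficient*, $\rho(\hat y_{cj},y_{cj}) = \hat y_{cj}y_{cj} /
(\sum_j \hat y_{cj}^2 + \sum_j y_{cj}^2)$, which is continuous and hence
rankable (a hard Dice loss is not).

The package bundles a synthetic data generator that reproduces this
annotation regime with known corruption (bounded morphological boundary
displacement; a "homogenization" clean-label control), a desk-scale
CPU training harness with tiny analytic-gradient predictors, an ablation
driver over the strategy grid, and the usual evaluation metrics
(pixel accuracy, Dice, mIoU, HD95).

## Worked example

```r
library(segrankloss)

train_data <- generate_dataset(synthetic_config(n_images = 60, seed = 101))
test_data  <- generate_dataset(synthetic_config(n_images = 60, seed = 901))

run_erm  <- train(train_data, predictor_spec(seed = 1),
                  strategy_config("erm", "none", "all", total_epochs = 30, seed = 1))
run_full <- train(train_data, predictor_spec(seed = 1),
                  strategy_config("atk_dec", "sm_inc", "bsigma",
                                  total_epochs = 30, seed = 1))

glance(evaluate(run_erm,  test_data))
#> # A tibble: 1 × 4
#>   accuracy  dice  miou  hd95
#>      <dbl> <dbl> <dbl> <dbl>
#> 1    0.982 0.719 0.691  23.4
glance(evaluate(run_full, test_data))
#> # A tibble: 1 × 4
#>   accuracy  dice  miou  hd95
#>      <dbl> <dbl> <dbl> <dbl>
#> 1    0.990 0.746 0.729  23.7

tail(tidy(run_full)[, c("epoch", "loss", "k", "alpha",
                        "discarded_corrupted_frac", "base_corruption")], 2)
#> # A tibble: 2 × 6
#>   epoch  loss     k alpha discarded_corrupted_frac base_corruption
#>   <int> <dbl> <int> <dbl>                    <dbl>           <dbl>
#> 1    28 0.714     5  1.66                    0.876          0.0178
#> 2    29 0.714     3  1                       0.875          0.0178
```

The full strategy trains on the same noisy annotations but reaches a
higher clean-mask test Dice (0.746 vs 0.719 here), and the history shows
why: among pixels the "bottom all but σ" filter discards, ~88% are
annotation-corrupted, against a ~1.8% corruption base rate. The
homogenized control (`synthetic_config(homogenize = TRUE)`) makes pixel
labels correct by construction, removing that enrichment mechanism; see
the methods vignette for what the filter does and does not buy in that
regime at desk scale.

`ablate()` runs a named grid of strategies over shared seeds and returns a
result-table-style tibble (divergent cells marked `"nc"`);
`autoplot()` on runs and ablation tables gives quick diagnostics; the
`inst/cli/segrankloss` script exposes `generate` / `train` / `ablate` /
`evaluate` for shell use with a YAML or JSON config.

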