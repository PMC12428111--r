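---
title: "Rank-selection loss envelopes for segmentation under annotation noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-selection loss envelopes for segmentation under annotation noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrankloss)
```

## The problem

Expert-annotated segmentation data in medical imaging has a characteristic
asymmetry: the *image-level* labels (which structures are present) are
reliable, while the *pixel-level* masks are noisy near region boundaries,
because annotation tools and time pressure favour simplified contours. A
training objective that weights every pixel equally therefore spends much of
its gradient budget fitting mislabeled boundary pixels.

`segrankloss` implements a loss-aggregation envelope that addresses both
levels by *ranking* individual losses:

* at the **image level**, the objective can concentrate on the hardest
  images — the mean of the top-$k$ per-image losses instead of the mean of
  all of them — on the premise that image labels are correct, so large
  per-image losses mark genuinely hard (informative) cases;
* at the **pixel level**, the objective can *discard* the highest pixel
  losses — on the premise that pixel labels are noisy, so extreme per-pixel
  losses mark annotation errors rather than signal.

## Rank aggregation and its smooth relaxation

For individual losses sorted ascending, $\ell_{[1]} \le \dots \le
\ell_{[N]}$, the implemented aggregators are the mean, the maximum
$\ell_{[N]}$, the average top-$k$
$\frac1k \sum_{i=N-k+1}^{N} \ell_{[i]}$,
and the general windowed mean
$\frac1k \sum_{i=i_0}^{i_0+k-1} \ell_{[i]}$,
which recovers the average top-$k$ at $i_0 = N-k+1$ and the "average
bottom-$k$" at $i_0 = 1$. The windowed mean can be written as a full sum
against the indicator of the rank window; the indicator is discontinuous in
$(i_0, k)$, and hard selection changes the selected set abruptly between
steps, which destabilises learning. Each indicator step is therefore
relaxed with a sigmoid $S_\alpha(i, k) = (1 + e^{-\alpha(i-k)})^{-1}$, and
the window with the *boxcar selector*
$\zeta_\alpha(i, i_0, k) = S_\alpha(i, i_0)\, S_\alpha(-i, -(i_0+k))$, a
product of a rising and a falling edge. The sharpness $\alpha$ trades
fidelity (large $\alpha$: near-exact selection) against smoothness (small
$\alpha$: weights spread over neighbouring ranks).

Numerical choices:

* The sigmoid is evaluated in a branch-safe form so arguments of magnitude
  up to $10^4$ (and beyond) saturate to exactly 0 or 1 rather than
  overflowing.
* `boxcar_selector()` follows the definition above verbatim: its value *at*
  the window edge is 0.5. When the selector weights integer ranks —
  `smoothed_select()` and the image-level weighting — both edges are
  shifted by half a rank ($i_0 - \tfrac12$, $i_0 + k - \tfrac12$), so every
  in-window integer rank sits strictly inside both edges. Without this
  centring the two edge ranks carry weight 0.5 forever and the smoothed
  windowed mean cannot converge to the exact one as $\alpha \to \infty$;
  with it, `smoothed_select(..., normalization = "effective_weight")`
  matches `select_average()` to $10^{-6}$ already at $\alpha = 100$.
* Three normalisations are exposed for the weighted sum: the total
  selector weight $\sum_i \zeta_\alpha(i)$ (default — a weighted mean,
  sharp-limit-consistent and scale-stable across schedules), the loss
  count $N$, and the window width $k$. The latter two reproduce the two
  printed conventions for the full-sum and windowed forms respectively.
* Ranking ties are stable: equal losses keep first-seen order, and new
  values insert after existing equal values in the epoch state.
* A single loss ($N = 1$) is its own mean, maximum and window.

## The nested segmentation objective

For segmentation the instance set factorises into $I$ images of $P$ pixels.
The envelope applies a pixel-level filter inside each image, reduces the
retained pixel losses to a per-image mean, and rank-weights the per-image
scalars across the epoch:

* **Pixel level** (`pixel_strategy`): `all`; `tk` — keep the top 10% of
  pixel losses; or `bsigma` — "bottom all but sigma": keep pixels with
  loss $\le$ the within-image mean plus one standard deviation. The
  standard deviation is the population one, and the comparison is
  non-strict, so a constant loss map (e.g. a freshly initialised model)
  retains every pixel and no image ever yields an empty retention.
* **Image level** (`image_strategy`): `erm` — all images; `atk` — the top
  10% window, active from the second epoch (ranks require losses from a
  previous pass); `atk_dec` — a window that starts at all images and
  shrinks linearly to the top 5% at the last epoch.
* **Smoothing** (`smoothing`): `none` — hard indicator weights; `sm` —
  $\alpha = 20$ throughout; `sm_inc` — $\alpha$ decreasing linearly from
  20 to 1, i.e. smoothing *increases* as the window sharpens, compensating
  the shrinking-window schedule.

Per-image losses are ranked *incrementally*: each batch's scalars are
inserted into an epoch-persistent sorted structure
(`incremental_sorted_insert()`), so ranking costs $O(k \times N)$ rather
than a full re-sort, and end-of-epoch selections provably equal offline
sorting (tested). Ranks computed mid-epoch are against losses of earlier
batches — deliberately stale, matching the incremental procedure; when the
state holds only part of the epoch, ranks are extrapolated to the full
image count by $r \cdot I/|\text{state}|$. The state is cleared at every
epoch boundary, and the first batch after a reset is weighted uniformly
(no ranking information exists yet). If every selector weight in a batch
underflows to zero — possible early under sharp top-$k$ — the batch falls
back to uniform weights rather than going gradient-dead, and the event is
flagged.

Selection is *stop-gradient*: selector weights and retention masks are
computed from loss values and treated as constants in the update step. The
objective is differentiable with respect to the predictions wherever ranks
and masks are fixed (verified by finite differences).

## Pixel losses

The per-pixel loss is
$\ell_j = \lambda_{CE}\, \ell_{CE}(\hat y_j, y_j) +
\lambda_{DC}\, (1 - f\, \rho_j)$,
with $\lambda_{CE} = 0.3, \lambda_{DC} = 0.7$ by default. $\ell_{CE}$ is
(optionally class-weighted) cross-entropy with probabilities clipped at
$10^{-12}$. $\rho_j$ is the per-pixel term of the *continuous Dice
coefficient* for the pixel's true class $c$:
$\rho(\hat y_{cj}, y_{cj}) = \hat y_{cj} y_{cj} \big/
\big(\sum_j \hat y_{cj}^2 + \sum_j y_{cj}^2\big)$ —
continuous, hence rankable, unlike the hard Dice loss. Evaluating $\rho$ at
the true class is the only attribution that makes $(1 - f\rho)$ a scalar
per pixel. Two scalings are exposed via `dice_factor`: the verbatim form
($f = 1$), under which a perfect prediction scores $\tfrac12$ per class
because the denominator counts both squared sums, and the standard
soft-Dice convention ($f = 2$, default for training), under which a perfect
prediction scores 0. Classes absent from both truth and prediction
contribute zero overlap and are excluded from the class average.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` produces textured grayscale images with elliptical
foreground regions whose mean intensities are class-specific; a
configurable fraction of "hard" images has compressed contrast. The
training annotation is the clean mask corrupted by *bounded morphological
boundary displacement*: for each region, a randomly selected fraction
(default 30%) of the boundary band is pushed inward or outward by up to
`boundary_noise_px` (default 3) pixels, with displacement direction varying
smoothly along the contour. This formalises, in a testable way, the
qualitative premise of boundary-imprecise expert annotation: corrupted
pixels are exactly recorded, provably local to boundaries, and their rate
grows with the displacement bound. Image-level labels always derive from
the clean mask (image-level annotation is assumed accurate).

The **homogenization control** (`homogenize = TRUE`) reproduces the
clean-label counterfactual: interiors of annotated regions are replaced by
a strongly blurred version of themselves, computed with mask-normalised
convolution so the annotated mask itself is the blending boundary and
background pixels are untouched. Because the data are altered to match the
annotation, the annotation becomes correct by construction; the generator
accordingly treats it as the effective ground truth and records zero
corruption. Under this control a filter that discards high-loss pixels can
only discard informative ones.

The generator does *not* emulate ultrasound speckle, MRI physics,
multi-channel acquisition, or annotator-specific bias; images are 8-bit
quantised so the PNG external format is lossless. Passing tests on this
generator demonstrates the *mechanism* — that statistics-based pixel
filtering preferentially discards mislabeled pixels and that this improves
clean-mask generalisation — not clinical-grade performance.

## The desk-scale harness

The bundled predictors are deliberately tiny so full experiments run in
seconds on one CPU: a softmax-linear model over per-pixel features (bias,
intensity, local means at three scales, affinely rescaled for
conditioning), and a variant adding a fixed random 3×3 filter bank with a
trainable linear readout. Gradients of the combined CE + continuous-Dice
objective are analytic (the Dice denominator couples all pixels of an
image; the implementation backpropagates it exactly) and checked against
finite differences. The optimiser is plain gradient descent, learning rate
5, batch size 5, per-epoch reshuffling under the strategy seed; runs are
bit-reproducible given the data, predictor and strategy seeds, and
training aborts with a diagnostic if the loss diverges
(`ablate()` marks such cells "nc" and continues).

One desk-scale deviation matters enough to flag prominently: the
**pixel-filter warmup**. Loss-rank selection presumes that a high loss
means something; from a *random* initialisation every foreground pixel of
a minority class scores a high loss, so filtering from epoch 0 discards
precisely the pixels the model has yet to learn and locks in a trivial
background predictor (we observed exactly this collapse). The reference
setting does not face this because its backbones are ImageNet-pretrained —
their initial losses are already informative. We therefore hold the pixel
filter at `all` for the first third of the schedule
(`pixel_warmup_epochs`, configurable), the same "losses must exist before
they can be ranked" logic the image-level schedule applies to its first
epoch. After warmup, with a roughly fitted model, the discarded set
concentrates overwhelmingly on corrupted pixels (measured enrichment:
~80–90% of discarded pixels are corrupted against a ~2% base rate).

Problem sizes used throughout the package's experiments were chosen so a
complete strategy comparison (2 conditions × 2 strategies × 5 seeds)
runs in a few minutes: 60 training and 20 test images of 64×64 pixels,
3 classes, 30 epochs, boundary noise 3 px on 30% of boundaries.

## Design choices on genuinely open points

* **Rank indexing** is 1-based throughout ("bottom-k" is $i_0 = 1$),
  consistent with the top window $i_0 = N-k+1$.
* **Falling edge sign**: the boxcar's second factor is
  $S_\alpha(-i, -(i_0+k))$; the sign convention is fixed by requiring the
  product to *be* a boxcar (rising edge times falling edge).
* **Shrinking-window interpolation** (`atk_dec`) and the $\alpha$ schedule
  are linear in the epoch index — the simplest monotone schedules
  consistent with "decreasing gradually".
* **Per-image ranking score** is the mean of the retained pixel losses —
  the scalar the envelope already computes; image-level continuous Dice
  does not additionally enter the ranking.
* **Epoch-persistent ranking** (rather than within-batch) follows from the
  incremental sorted structure; it is an interpretation, exposed in
  `nested_loss()`'s contract and tested against offline sorting.
* **Metric conventions** (macro averaging over classes present in truth or
  prediction, background excluded from Dice/IoU/HD95 means by default,
  absence conventions for Dice and HD95, HD95 percentile by linear
  interpolation) are all explicit arguments, since result-table
  conventions are rarely stated in the literature.

## Known limitations

* The predictors are per-pixel classifiers with small receptive fields;
  they cannot express shape priors, so absolute scores are far below what
  segmentation backbones reach. The package measures *relative* effects of
  aggregation strategies, which is what it is for.
* With such capacity-limited models, trimming high-loss pixels can help
  even on clean labels: on hard (low-contrast) images a few saturated
  clipped cross-entropy pixels ($-\log 10^{-12} \approx 27.6$) can dominate
  the image gradient and stall its optimisation, and discarding them acts
  as robust trimming that lets a misspecified model partially fit the hard
  regime. The clean-label control therefore isolates the filter against
  the same image-level strategy (with vs without `bsigma`), and even so
  its advantage need not fully vanish at desk scale — a regime difference
  from large pretrained backbones, for which loss ranks are informative
  from the start and clean-label trimming only removes signal.
* HD95 is 2-D and computed by exact pairwise boundary distances — fine at
  desk scale, quadratic in boundary length.
* The smoothed selector weights are a relaxation for *stability*, not a
  differentiable-sorting scheme: gradients do not flow through ranks.
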