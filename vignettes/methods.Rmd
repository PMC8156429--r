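---
title: "Methods: spectral CNN regression of grape ripeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral CNN regression of grape ripeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures `vitispec` implements, the
assumptions behind them, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The problem

Grape ripeness is tracked through sugar content (°Brix) and pH, classically
measured by refractometry and potentiometry on crushed berries. Line-scan
hyperspectral imaging in reflectance mode offers a nondestructive
alternative: each sample of 6–12 berries yields a mean reflectance spectrum
(1040 bands by default), and a regression model maps that spectrum to the
two targets. The hard part is robustness: targets and spectra both shift
between vintages (climate) and varieties (genetics), so a model trained on
one cohort must be probed on others.

## Reflectance calibration

Raw line-scan intensities are converted to reflectance per position $x$ and
band $\lambda$:

$$R(x,\lambda) = \frac{GI(x,\lambda) - DI(x,\lambda)}{SI(x,\lambda) - DI(x,\lambda)}$$

with $DI$ the dark-current frame (shutter closed) and $SI$ the white
reference. Two numerical choices:

* **No clipping.** Reflectance above 1 is physically meaningful (specular
  highlights on the berry cuticle) and is preserved.
* **Band validity mask.** A band is invalid when the white dynamic
  $SI - DI$ falls at or below $\varepsilon = 10^{-6} \cdot \max(SI - DI)$
  anywhere along the scan. Invalid bands are flagged (`NA`), not clipped, and
  downstream datasets drop masked bands uniformly. The relative threshold
  makes the mask invariant under common affine rescaling of all three
  frames, which the calibration itself also satisfies.

Berry segmentation is out of scope; `extract_mean_spectrum()` is a minimal
mask-and-average hook (positions whose broadband mean exceeds a threshold
are averaged).

## Spectral preprocessing

Exactly one method is applied per experiment — the three are alternatives to
be compared, not a chain:

* **MSC.** Each spectrum $s$ is regressed on a reference $r$ by OLS over
  bands, $s \approx a + b\,r$, and corrected to $(s - a)/b$. The reference
  is always the arithmetic mean of the *training* spectra, frozen and
  carried in the model artifact, so validation/test application can never
  leak information. For a spectrum that is exactly an affine transform of
  the reference the correction is exact; a near-zero slope
  ($|b| \le 10^{-8}$) is a degenerate-spectrum error.
* **Min–max normalization.** Per spectrum, map the minimum to 0 and the
  maximum to 1. Constant spectra are rejected.
* **Savitzky–Golay.** Local least-squares polynomial fit of order 2 in a
  15-point moving window; the modelled variant uses the first derivative,
  which removes additive baselines and sharpens band structure. Two
  decisions the classical filter leaves open:
  * *Edges.* The first/last 7 bands use truncated asymmetric windows (the
    polynomial is fit on the available points), keeping the output length
    equal to the input length without padding artifacts. This differs from
    implementations that anchor a full-width asymmetric window at the edge;
    the truncated-window convention is what the package's brute-force test
    oracle also computes, band by band.
  * *Units.* Derivatives are taken with respect to band index (unit
    spacing), not nanometres — the physical wavelength grid is optional
    metadata and all algorithms operate on band index.

## Stratified splitting

Within each vintage (crossed with variety when a dataset mixes varieties),
reference values are cut into five strata at the 20/40/60/80th percentiles.
Within every stratum, `round(0.1 n)` samples go to the test set and another
`round(0.1 n)` to validation, sampled without replacement under a seed; the
rest train the model. Choices the contract leaves open, fixed here:

* Percentiles are estimated by linear interpolation between closest ranks
  (R's type-7 quantile), shared project-wide with the evaluation percentile
  curves.
* Rounding is half-up per cell, with a minimum of one test and one
  validation sample when the cell has at least 3; smaller cells contribute
  to training only.
* Values tied with a cut fall in the lower bin, so a degenerate
  all-identical group collapses into bin 1.
* The stratification variable is the target being modelled; a split shared
  between both targets stratifies on sugar (configurable, since either
  convention is defensible).

`repeated_splits()` generates independent splits seeded `base_seed + k - 1`
to check that a single-split result is not a lucky draw.

## The 1D CNN

Fixed topology (only sizes are tuned):

```
input (B x 1)
  -> conv1d(filters1, kernel1, stride 1, 'same') + ReLU -> batch norm
  -> max-pool 2
  -> conv1d(filters2, kernel2, stride 1, 'same') + ReLU -> batch norm
  -> max-pool 5 -> dropout(dropout1)
  -> flatten (filters2 * floor(floor(B/2)/5))
  -> dense(neurons) + ReLU -> dropout(dropout2)
  -> dense(1, linear)
```

Training minimizes MSE with Adadelta (decay 0.95, stability constant
$10^{-7}$; only the learning rate is tuned) at the tuned batch size,
stopping early when validation MSE has not improved for `patience` epochs
and restoring the best-epoch weights. Defaults: 500 epochs, patience 50.
Weights are Glorot-uniform; all randomness (init, shuffling, dropout masks)
comes from R's RNG, so runs are bit-reproducible under a seed.

Design decisions worth recording:

* **Block order** is conv → ReLU → batch norm (the batch-norm layer sits
  after each convolution block; its position relative to the activation is
  a convention, chosen here to match the common Keras idiom of an activated
  convolution followed by normalization).
* **Dense hidden activation** is ReLU, matching the convolutional blocks.
* **No target standardization.** Targets stay in °Brix / pH units so every
  reported RMSE is directly interpretable. Because Adadelta's early steps
  are deliberately conservative, the output bias is initialized to the
  training-target mean; the network then learns deviations rather than
  spending thousands of steps closing a ~19 °Brix offset.
* **One model per target** (a single linear output neuron): sugar and pH
  get separate training runs.
* **Pooling truncates** (floor) on non-divisible lengths, so any band count
  B ≥ 10 is legal; the flattened length is
  `floor(floor(B/2)/5) * filters2` (6240 for B = 1040, filters2 = 60).
* The implementation is a from-scratch RcppArmadillo kernel (forward,
  backward, batch-norm statistics, Adadelta state) — there is no
  deep-learning framework dependency, which keeps the package installable
  anywhere R and a BLAS are available and makes training deterministic.

## Bayesian hyperparameter optimization

Nine tunables (two filter counts, two kernel sizes, dense width, two
dropout rates, learning rate, batch size) are searched over their bounded
ranges. The optimizer:

* encodes points onto the unit cube (integer dimensions by continuous
  relaxation, rounded at evaluation);
* fits a zero-mean Gaussian process with a Matérn-5/2 ARD kernel plus a
  fitted noise term on standardized objective values, kernel
  hyperparameters by marginal-likelihood maximization (L-BFGS-B,
  multistart);
* maximizes expected improvement,
  $\mathrm{EI} = (f^* - \mu - \xi)\,\Phi(z) + \sigma\,\phi(z)$ with
  $z = (f^* - \mu - \xi)/\sigma$ and $\xi = 0.01$, over random candidates
  with a local polish from the best few, never re-proposing an
  already-evaluated integer-decoded point;
* records failed/diverged trainings with a large finite penalty, excluded
  from surrogate fitting.

The objective is the validation RMSE at the best epoch of a single training
run per candidate (no cross-validation — the experiment design uses one
held-out validation set). Learning rate and dropout are searched on the
linear scale; their ranges are narrow enough that log-scaling would change
little. Reference budgets are 20 random + up to 200 GP iterations;
desk-scale defaults in the workflow layer are 8 + 12, because a full budget
means hundreds of CNN trainings.

The exact kernel, $\xi$, and acquisition optimizer are exposed as
configuration, not asserted as anyone else's choices.

## Transfer learning

`init_from_pretrained()` copies every weight, including batch-norm running
statistics, into an architecturally identical model — predictions before
fine-tuning are exactly the source model's. `fine_tune()` then retrains all
layers (no freezing) on the new vintage under the usual early-stopping
contract. The orchestrated experiment compares (a) a base model trained on
all source + fine-tune vintages pooled against (b) pretrain-on-source then
fine-tune-on-newest, both evaluated on a held-out vintage, reporting the
relative RMSE drop.

## Evaluation

RMSE is reported in natural units — RMSEV on validation, RMSEP on test —
with 3 decimals in printed reports; absolute percentage errors
($100\,|\hat y - y|/y$) are summarized at the 5/25/50/75/95th percentiles
(1 decimal). Grouped reports (per variety or vintage) conserve the pooled
squared-error sum. `relative_improvement()` computes
$100\,(\mathrm{RMSE}_{base} - \mathrm{RMSE}_{new})/\mathrm{RMSE}_{base}$;
for the published RMSEP pairs it reproduces the ~22 % (sugar) and ~18 %
(pH) transfer-learning drops.

## The synthetic-data generator

Real berry spectra are driven by overlapping absorption features whose
depths co-vary with composition, modulated by berry size and curvature. The
generator emulates exactly that structure:

$$s_i = m_i\Big(\mathrm{baseline} + \sum_{k=1}^{8} (\alpha_k + \beta_k\,
\mathrm{sugar}_i + \gamma_k\,\mathrm{pH}_i)\, e^{-(t-\mu_k)^2/2\sigma_k^2}
\Big) + c_i + \varepsilon_i$$

with $m_i$ log-normal multiplicative scatter ($\sigma_{\log} = 0.1$), $c_i$
a normal additive offset (SD 0.02 reflectance units), per-band Gaussian
noise (SD 0.005), and reference values = true targets + measurement noise
(0.5 °Brix / 0.05 pH), clamped to the configured ranges
([5.5, 30.3] °Brix, [2.6, 5.0] pH — the envelopes of a realistic
multi-variety campaign spanning veraison to maturity). Eight Gaussian bands
(three sugar-linked, two pH-linked, three inert) give the network
non-trivial structure to find while staying desk-scale; the default group
design is one variety with six vintages and two with four, with °Brix-scale
vintage and variety mean shifts. The scatter model is chosen so that MSC is
the *analytically correct* corrector — a generator property the tests
exploit (correcting with the true mean reference shrinks scatter-induced
variance by well over an order of magnitude).

What the generator does **not** emulate: radiative-transfer physics,
spatial berry texture, instrument line-spread, wavelength-dependent noise,
or non-linear target–spectrum couplings. Passing tests therefore
demonstrate that the pipeline's machinery is correct and that the network
can recover a known linear-in-targets spectral encoding under realistic
corruption — they do not certify field performance on real grapes, whose
reference data are not distributed with the package.

With scatter and noise off, the target → spectrum map is exactly linear, so
an OLS/ridge probe is an oracle for the recoverable signal; the CNN is
expected to approach it, and on the default recovery experiment it does
(test RMSE close to the reference measurement noise).

## Problem sizes used by tests and the acceptance script

The test-suite experiments are sized for a single CPU: parameter recovery
uses n = 1200 samples on the full 1040-band grid with ≤ 120 epochs and
small filter counts; the transfer experiment uses 256 bands, ~700 samples
and 5 fine-tuning seeds; the tuner comparison runs 10 repeats of a
(10 random + 30 GP) budget on a 2-d toy objective. These sizes are the
package's chosen desk-scale study conditions; the same code runs the
reference budgets (20 + 200, full ranges) unchanged when given them.

## Known limitations

* Training is single-threaded CPU; paper-scale tuning budgets (hundreds of
  trainings at up to 256 filters) are expensive, though desk-scale budgets
  reproduce the qualitative conclusions.
* The GP surrogate's marginal-likelihood surface is multimodal; a small
  multistart is used, not a global optimizer.
* Batch-norm statistics are updated with momentum 0.99, so very short
  trainings (a few dozen steps) evaluate with partially converged running
  statistics — histories report exactly what inference-mode evaluation saw.
* The wavelength range of the spectrograph is not modelled; all algorithms
  operate on band index, and physical wavelengths are optional metadata.
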