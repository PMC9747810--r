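---
title: "Minimum convergence sample estimation: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum convergence sample estimation: models, defaults and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Before labeling a dataset for supervised training, one would like to know
how many labels are worth paying for. For a fully connected classifier
$f$ on a dataset $X$, the *minimum convergence sample* (MCS) is the
smallest $n$ such that a random labeled subset of size $n$ trains $f$
into a non-trivial classifier — one whose held-out area under the ROC
curve exceeds 0.5:

$$\mathrm{MCS} := \arg\min_n \Big( \mathbb{E}\big[\mathrm{AUC}(f_{X_n,y_n})\big] > 0.5 \Big).$$

The MCS needs labels to measure. The *minimum convergence sample
estimate* (MCSE) approximates it from unlabeled data alone: train a
matched autoencoder $g$ — encoder widths equal to the classifier trunk,
bottleneck of dimension 3 — on increasing subsets, record its held-out
reconstruction loss $L(n)$, smooth the curve, and take the sample size at
the inflection of the loss curve:

$$\mathrm{MCSE} := \arg\max_n \frac{d^2 L}{d n^2}.$$

Above the MCSE, classifier generalization is hypothesised to track the
autoencoder's loss through a scaling constant $\beta$:

$$\frac{d\,\mathrm{AUC}}{dn}\,\mathrm{AUC}(f_n) \simeq
\begin{cases} 0 & n < \mathrm{MCSE} \\
-\beta\, \frac{dL}{dn}\, L(g_n) & n \ge \mathrm{MCSE}, \end{cases}$$

whose integrated form is an affine relation between mean AUC and mean
loss on the post-MCSE segment. The package fits it by least squares
(`fit_extrapolation()`) and inverts it (`required_sample_size()`) to
answer "how many samples for AUC $\ge$ 0.9?".

## Pipeline and module map

1. **Synthetic data** — `synthetic_spec()`, `generate_hypercube_dataset()`,
   `mislabel()`, `load_csv_dataset()`.
2. **Networks** — `network_spec()`, `train_config()`,
   `build_classifier()`, `build_autoencoder()`, `train_classifier()`,
   `train_autoencoder()` (RcppArmadillo training core).
3. **Sweep** — `sweep_schedule()`, `run_sweep()`, `aggregate_sweep()`,
   CSV + JSON sidecar I/O.
4. **Curves** — `fit_learning_curve()`, `estimate_mcse()`,
   `estimate_auc_inflection()`.
5. **Statistics** — `split_and_correlate()`, `fit_extrapolation()`,
   `required_sample_size()`, `correlation_table()`.
6. **Pipeline/CLI** — `mcse_config()`, `cmd_simulate()`, `cmd_sweep()`,
   `cmd_estimate()`, `cmd_report()`, and the thin wrapper in
   `inst/cli/mcse.R`.

## The synthetic generator

Each class is centred on a distinct vertex of an
`n_informative`-dimensional hypercube with side `class_sep`; samples get
isotropic unit-variance Gaussian scatter on informative coordinates, and
the remaining `n_features - n_informative` coordinates are standard
Gaussian noise independent of class. Labels are balanced to within one
sample, and a `mislabel_rate` fraction of labels can be replaced by a
uniformly random *different* class.

Design choices worth stating:

* **Vertices are drawn at random (seeded), not in Gray-code order.** A
  Gray-code walk from vertex 0 over classes $0..K-1$ only ever exercises
  the low $\lceil \log_2 K \rceil$ bits, so informative dimensions beyond
  the fourth would carry no between-class variance at all for ten
  classes. Random distinct vertices keep every informative dimension
  class-relevant in expectation, which is what makes the informative
  count a meaningful difficulty axis.
* **`class_sep` is measured in units of the within-class standard
  deviation** (fixed at 1). The default `class_sep = 1` places adjacent
  centroids one within-class standard deviation apart: a hard but
  learnable task. The default `n_informative = 32` of 784 features
  mirrors a high-dimensional tabular/imaging regime where most
  dimensions are nuisance.
* **Mislabeling never reproduces the original label**, so `rate` is
  exactly the expected fraction of wrong labels.

What the generator emulates: clustered class structure, nuisance
dimensions, annotation noise. What it does not: pixel correlation and
smooth image manifolds, heavy-tailed or heteroscedastic noise,
class imbalance, covariate shift. Tests passing on this generator say the
estimator behaves as designed on clustered Gaussian data; they do not
certify performance on natural images.

## Networks and training

Both networks share one `network_spec()`: classifier
`input_dim -> h1 -> h2 -> h3 -> n_classes`, autoencoder
`input_dim -> h1 -> h2 -> h3 -> latent -> h3 -> h2 -> h1 -> input_dim`,
ReLU between layers. The bottleneck default of 3 balances over- and
under-compression. Training uses Adam (`learning_rate = 1e-3`), batch 32,
50 epochs by default, softmax cross-entropy for $f$ and mean squared
error for $g$; features are standardised with *training-split* statistics
before both networks so reconstruction losses share a scale (an untrained
network then scores $\approx 1.0$, the variance baseline). Weights are
initialised with the standard uniform fan-in rule
$U(\pm 1/\sqrt{\mathrm{fan\_in}})$ of the major deep-learning frameworks.
All randomness (init, shuffling) flows from one integer seed through a
dedicated generator, so a (data, spec, config, seed) tuple reproduces the
trained model exactly on a single CPU thread. `early_stop_patience`
optionally monitors a 10% validation carve-out and restores the best
weights; the default (0, fixed epochs) keeps replicates exchangeable.

AUC is macro one-vs-rest (rank-based Mann–Whitney per class, averaged
over classes present in the test split; absent classes are skipped with a
warning). Reconstruction loss is evaluated on the held-out test features,
mirroring the classifier protocol.

## The sweep

`run_sweep()` holds out one fixed test split (default: 10,000 rows or 20%
of the data, whichever is smaller), then for each sample size in a
doubling schedule (16, 32, ... up to the pool, final entry the full pool)
and each of `n_bootstrap` replicates draws that many rows *without
replacement* from the pool, trains a fresh classifier and a fresh
autoencoder on the same draw, and records held-out AUC and loss.
Without-replacement draws match the definition of the MCS (a random
subset of $X$); sharing the draw between the two networks pairs the
curves and reduces comparison variance. Per-cell seeds are derived
injectively from `(base_seed, size index, replicate)`, so any cell can be
recomputed independently — which is also how interrupted sweeps resume
(`completed =`) to bitwise-identical results.

## Curve smoothing and the inflection

The per-size replicate *means* are smoothed with a natural cubic spline
(`stats::splinefun(method = "natural")`) in $x = \log_2 n$:

* **Why $\log_2 n$:** the schedule doubles, so knots are equally spaced
  on this axis; derivatives with respect to raw $n$ would be dominated by
  the smallest sizes.
* **Why the mean curve, not per-replicate fits:** 13 means are what the
  design measures; per-replicate spline refits are a possible uncertainty
  extension, deliberately out of scope.
* The argmax of the second derivative is searched on a dense interior
  grid (2001 points), **excluding half a knot spacing at each end**,
  where natural boundary conditions force curvature to zero by
  construction rather than by data. Exact ties break to the smallest
  sample size — a conservative lower bound for data collection.
* **Well-definedness:** the curvature peak must exceed `kappa = 3` times
  the *median* absolute curvature over the grid, plus an absolute
  round-off floor so linear/flat curves are never declared inflections. A
  median was chosen over an interquartile range because a clean logistic
  inflection concentrates its curvature: its peak is only about twice the
  IQR of $|d^2|$ across the grid, so an IQR-based threshold at 3 rejects
  textbook inflections, while the median of $|d^2|$ separates
  concentrated peaks from the everywhere-wiggly curvature of
  noise-dominated splines.
* **Error band:** the loss curve evaluated at $e^{\ln(\mathrm{MCSE})\pm 1}$
  (i.e. MCSE$/e$ and MCSE$\cdot e$), clipped to the sampled range. This
  reconciles the two phrasings of the band found in descriptions of the
  method ("$\pm \ln n$" and "log(MCSE $\pm$ 1)") into one computable rule.
* The AUC curve mirrors the loss curve, so its inflection is located as
  the *minimiser* of the second derivative; it is used only to check that
  the two transitions land at similar sample sizes.

Degenerate inputs: fewer than 4 sizes are refused (no curvature
estimate); evaluation outside the knot range is refused; an AUC curve
constant at 0.5, or any curve with sub-round-off curvature, yields
`well_defined = FALSE` — a finding, reported with exit code 0 by the CLI.

## Correlation report and extrapolation

`split_and_correlate()` partitions the *replicate-level* (AUC, loss)
pairs at the MCSE (`n >= mcse_n` counts as post) and reports squared
Pearson correlation, Kendall's $\tau$ and Spearman's $\rho$ of AUC
against negated loss, so all three are positive when higher AUC
accompanies lower loss. Replicate-level points are used because a handful
of per-size means cannot support stable coefficients; sides with fewer
than 3 points or degenerate variance report `NA` (undefined, not zero).
No multiple-testing correction is applied; the report is descriptive.

`fit_extrapolation()` fits mean AUC against mean loss over post-MCSE
sizes; $\beta$ is the negated slope, and a non-negative slope flags the
fit invalid. `required_sample_size()` inverts the fit to a loss level and
then inverts the monotone-decreasing segment of the loss curve (global
maximum down to global minimum on a dense grid) to a sample size; a
target below the observed loss floor is reported `unreachable` rather
than extrapolated.

## Desk-scale study profile

The default simulated study used by the test suite and the acceptance
script is scaled to a single CPU: 6,000 samples (1,200 held out), sizes
$16, 32, \ldots, 4096$, 10 bootstrap replicates, hidden trunk
(32, 16, 8), 20 epochs. Epoch budgets between 10 and 100 and trunks from
(16, 8, 4) to (64, 32, 16) produce the same loss-curve shape on this
generator, so the small profile is representative, and a full-scale
profile (50 replicates, 13 sizes) is a configuration change, not a code
change.

## Observed behaviour of the default study, and limitations

On the default generator the held-out autoencoder loss shows a two-phase
shape: a quick phase — a steep decline from an overfitting bump at the
smallest sizes — and a slow phase that approaches the variance baseline.
The curvature maximum therefore sits at the bend between the phases, at a
few tens of samples, and the correlation split places almost the whole
sweep on the post side. Two structural facts drive this:

* With `class_sep = 1` and 32 informative of 784 dimensions, the
  between-class variance available to a 3-dimensional bottleneck is below
  1% of total variance (the between-class spectrum has rank at most
  $K - 1$). A rank-3 PCA oracle on the same data shows the same convex
  decay with a sub-1% structure-driven drop only at the largest sizes.
  Spiked-covariance detectability ($n^* \sim p/\theta^2$) implies that
  any configuration whose unsupervised transition is pushed to hundreds
  of samples necessarily has an amplitude too small to dominate the
  overfitting decay — so on this generator family the inflection tracks
  the end of the quick phase rather than a late structure-discovery
  event.
* The classifier, having labels, extracts signal from the smallest sizes
  onward (AUC is already above 0.5 at $n = 16$ and rises smoothly), so
  the dataset's own MCS sits at the very start of the schedule —
  consistent with the small MCSE the estimator reports. Estimator and
  data agree with each other; configurations reported elsewhere for
  superficially similar synthetic studies depend on generator and
  optimizer settings that are not derivable from their descriptions.

Other known limitations: single-threaded CPU training only; no
convolutional/recurrent/variational variants; fully connected inputs must
be pre-flattened vectors; MCSE uncertainty is summarised by the loss band
only (no nested bootstrap); and label-quality problems are modelled only
as uniform mislabeling.
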