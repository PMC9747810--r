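# mcse: minimum convergence sample estimation for fully connected classifiers

How many labeled samples does a neural-network classifier need before it
starts to generalize? `mcse` estimates that number **from unlabeled data
alone**, for researchers (e.g. in medical imaging or clinical ML) who
must budget an expensive labeling effort before it begins.

For a fully connected classifier *f* on data *X*, the *minimum
convergence sample* (MCS) is the smallest *n* such that a random labeled
subset of size *n* trains *f* into a non-trivial classifier:

    MCS := argmin_n ( E[ AUC(f_{X_n, y_n}) ] > 0.5 )

The package estimates it by training a **matched autoencoder** *g*
(encoder widths equal to the classifier trunk, 3-dimensional bottleneck)
across a doubling schedule of sample sizes with bootstrapped replicates,
smoothing the held-out reconstruction-loss curve *L(n)* with a natural
cubic spline in log2(n), and locating the inflection:

    MCSE := argmax_n  d²L/dn²

Above the MCSE, classifier generalization tracks the autoencoder loss via
a scaling constant β (`dAUC/dn · AUC ≈ −β · dL/dn · L`), which the
package fits as an affine AUC-vs-loss relation and inverts to the sample
size required for a target AUC.

What ships:

* a seeded **hypercube-cluster synthetic generator** (class centroids at
  random distinct hypercube vertices, Gaussian scatter, nuisance
  dimensions, controllable label noise) plus CSV ingestion for your own
  feature matrices;
* an **RcppArmadillo training core** for the paired classifier /
  autoencoder (ReLU, Adam, deterministic per seed);
* the **bootstrapped sample-size sweep** with resumable, tidy CSV output;
* the **spline inflection estimator** with a well-definedness verdict and
  an error band (loss at MCSE/e and MCSE·e);
* **pre/post-MCSE correlation reports** (R², Kendall's τ, Spearman's ρ)
  and the **β extrapolation** with `required_sample_size()`;
* a pipeline API (`cmd_simulate()` → `cmd_sweep()` → `cmd_estimate()` →
  `cmd_report()`) and a thin CLI (`inst/cli/mcse.R`).

## Worked example

```r
library(mcse)

spec <- synthetic_spec(n_features = 64, n_informative = 8, n_classes = 4,
                       class_sep = 3, n_samples = 3000, seed = 1)
dataset <- generate_hypercube_dataset(spec)

sweep <- run_sweep(
  dataset,
  schedule = sweep_schedule(sample_sizes = c(16, 32, 64, 128, 256, 512, 1024),
                            n_bootstrap = 5, test_size = 600, base_seed = 1),
  net_spec = network_spec(64, hidden_sizes = c(32, 16, 8), latent_dim = 3,
                          n_classes = 4),
  config = train_config(epochs = 30))

aggregate_sweep(sweep)
#> # A tibble: 7 × 6
#>       n n_replicates auc_mean   auc_sd loss_mean loss_sd
#>   <int>        <int>    <dbl>    <dbl>     <dbl>   <dbl>
#> 1    16            5    0.658 0.0420       1.27  0.0331
#> 2    32            5    0.677 0.0417       1.15  0.0282
#> 3    64            5    0.821 0.0269       1.05  0.0186
#> 4   128            5    0.942 0.0256       1.01  0.00803
#> 5   256            5    0.993 0.00359      0.970 0.0138
#> 6   512            5    0.999 0.000684     0.943 0.0161
#> 7  1024            5    1.000 0.000284     0.931 0.0111

mcse_report(sweep, target_auc = 0.95)
#> == MCSE report ==
#> <mcse_estimate>
#>   MCSE: n = 64 (log2 = 6.00), loss 1.051
#>   band: n in [24, 174], loss in [1.203, 0.9945]
#> <mcse_inflection> AUC inflection at n = 128 (log2 = 7.00) [not well defined]
#> Correlation (replicate-level AUC vs -loss):
#> # A tibble: 2 × 5
#>   side  n_points    r2 kendall_tau spearman_rho
#>   <chr>    <int> <dbl>       <dbl>        <dbl>
#> 1 pre         10 0.175        0.2         0.309
#> 2 post        25 0.756        0.74        0.905
#> <mcse_extrapolation> AUC = 2.3377 -1.413 * loss  (beta = 1.413)
#>   fit R^2 = 0.853 over 5 post-MCSE sizes, loss domain [0.9311, 1.051]
#> Required sample size:
#> # A tibble: 1 × 4
#>   target_auc loss_target required_n unreachable
#>        <dbl>       <dbl>      <dbl> <lgl>
#> 1       0.95       0.982       211. FALSE
```

Reading it: the reconstruction-loss curve bends from its quick phase into
its slow phase at **n = 64** — the MCSE, with an error band spanning
24–174 samples — and the classifier's own AUC inflection lands one
doubling away, at 128. Below the MCSE the replicate-level AUC/loss pairs
are weakly related (R² 0.18); above it they correlate strongly (R² 0.76,
ρ 0.90), so the fitted line AUC = 2.34 − 1.41·loss is trusted and
inverted: reaching AUC ≥ 0.95 needs roughly **211 labeled samples**,
consistent with the aggregate table (AUC 0.94 at n = 128, 0.99 at
n = 256). `autoplot()` methods draw the sweep, the smoothed curve with
its derivatives and band, and the extrapolation fit.

On unstructured data the estimator refuses to guess: the curvature peak
falls below the noise floor and the report carries
`well_defined = FALSE` (an exit-code-0 *finding* in the CLI).

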