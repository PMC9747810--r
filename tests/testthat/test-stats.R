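# Build a synthetic sweep table directly: replicate-level (auc, loss)
# records with known structure, no network training involved.
fake_sweep <- function(ns = 2^(4:12), reps = 8, seed = 1,
                       auc_fun, loss_fun, noise = 0) {
  set.seed(seed)
  tidyr::expand_grid(n = ns, replicate = seq_len(reps)) |>
    dplyr::mutate(seed = dplyr::row_number(),
                  auc = auc_fun(n) + rnorm(dplyr::n(), 0, noise),
                  loss = loss_fun(n) + rnorm(dplyr::n(), 0, noise))
}

test_that("perfect monotone post-MCSE points give unit coefficients", {
  sw <- fake_sweep(auc_fun = function(n) 0.5 + 0.04 * log2(n),
                   loss_fun = function(n) 2 - 0.05 * log2(n))
  cr <- split_and_correlate(sw, 256)
  post <- cr[cr$side == "post", ]
  expect_equal(post$r2, 1, tolerance = 1e-12)
  expect_equal(post$kendall_tau, 1, tolerance = 1e-12)
  expect_equal(post$spearman_rho, 1, tolerance = 1e-12)
  expect_equal(cr$n_points[1] + cr$n_points[2], nrow(sw))
})

test_that("independently shuffled pre-MCSE pairs look uncorrelated", {
  set.seed(11)
  sw <- fake_sweep(auc_fun = function(n) 0.5, loss_fun = function(n) 1.5,
                   noise = 0.05)
  cr <- split_and_correlate(sw, 1e9) # everything on the pre side
  pre <- cr[cr$side == "pre", ]
  # oracle: permutation null of the squared correlation
  d <- sw[is.finite(sw$auc), ]
  null_r2 <- replicate(1000, cor(d$auc, sample(-d$loss))^2)
  expect_lt(pre$r2, quantile(null_r2, 0.95) + 0.05)
  expect_lt(pre$r2, 0.15)
})

test_that("degenerate variance yields undefined coefficients, not zero", {
  sw <- fake_sweep(auc_fun = function(n) 0.75, # all aucs equal
                   loss_fun = function(n) 2 - 0.05 * log2(n))
  cr <- split_and_correlate(sw, 256)
  expect_true(all(is.na(cr$r2)))
  expect_true(all(is.na(cr$kendall_tau)))
  # too few points on a side is undefined too
  sw2 <- fake_sweep(reps = 1, auc_fun = function(n) 0.5 + 0.01 * log2(n),
                    loss_fun = function(n) 2 - 0.05 * log2(n), noise = 0.01)
  cr2 <- split_and_correlate(sw2, 32) # one point on the pre side
  expect_true(is.na(cr2$r2[cr2$side == "pre"]))
  expect_equal(cr2$n_points[cr2$side == "pre"], 1)
})

test_that("sign coherence: falling loss with rising AUC gives positive coefficients", {
  sw <- fake_sweep(auc_fun = function(n) 0.5 + 0.04 * log2(n),
                   loss_fun = function(n) 2 - 0.05 * log2(n), noise = 0.005,
                   seed = 3)
  cr <- split_and_correlate(sw, 64)
  post <- cr[cr$side == "post", ]
  expect_true(all(c(post$r2, post$kendall_tau, post$spearman_rho) > 0))
})

test_that("beta is recovered within 5% from noisy affine sweeps", {
  # oracle: the generating slope b, over 20 noise seeds
  b <- 0.8; a <- 1.9
  errs <- sapply(1:20, function(s) {
    sw <- fake_sweep(seed = s, reps = 10,
                     loss_fun = function(n) 2 - 0.09 * log2(n),
                     auc_fun = function(n) a - b * (2 - 0.09 * log2(n)),
                     noise = 0.002)
    fit <- fit_extrapolation(sw, 64)
    abs(fit$beta - b) / b
  })
  expect_lt(median(errs), 0.05)
  expect_lt(max(errs), 0.05)
})

test_that("extrapolation requires 3 post sizes and flags rising loss", {
  sw <- fake_sweep(auc_fun = function(n) 0.5 + 0.04 * log2(n),
                   loss_fun = function(n) 2 - 0.05 * log2(n))
  expect_error(fit_extrapolation(sw, 1e9), ">= 3 post-MCSE")
  # AUC *decreasing* as loss falls -> invalid fit
  sw_bad <- fake_sweep(auc_fun = function(n) 1 - 0.03 * log2(n),
                       loss_fun = function(n) 2 - 0.05 * log2(n))
  expect_warning(fit_bad <- fit_extrapolation(sw_bad, 64), "invalid")
  expect_false(fit_bad$valid)
  expect_error(required_sample_size(fit_bad,
                                    fit_learning_curve(2^(4:12), 2 - 0.05 * (4:12)),
                                    0.9), "invalid")
})

test_that("required_sample_size inverts the fit self-consistently", {
  ns <- 2^(4:12)
  loss_fun <- function(n) logistic_loss(log2(n), x0 = 7, lo = 0.8, hi = 2)
  auc_fun <- function(n) 1.55 - 0.75 * loss_fun(n)
  sw <- fake_sweep(auc_fun = auc_fun, loss_fun = loss_fun)
  est_split <- 128
  fit <- fit_extrapolation(sw, est_split)
  curve <- fit_learning_curve(ns, loss_fun(ns))

  # target equal to the mean AUC at a sampled size returns that size
  target_n <- 1024
  req <- required_sample_size(fit, curve, auc_fun(target_n))
  expect_false(req$unreachable)
  expect_lt(abs(log2(req$required_n) - log2(target_n)), 1)

  # a target midway between AUC at the split and the max lies between them
  mid <- (auc_fun(est_split) + auc_fun(max(ns))) / 2
  req_mid <- required_sample_size(fit, curve, mid)
  expect_gt(req_mid$required_n, est_split)
  expect_lt(req_mid$required_n, max(ns))

  # a target above the fit's value at the minimal loss is unreachable
  req_hi <- required_sample_size(fit, curve, 0.999)
  expect_true(req_hi$unreachable)

  expect_error(required_sample_size(fit, curve, 0.5), "strictly between")
  expect_error(required_sample_size(fit, curve, 1), "strictly between")
})

test_that("correlation_table renders one wide row per grid value", {
  sw <- fake_sweep(auc_fun = function(n) 0.5 + 0.04 * log2(n),
                   loss_fun = function(n) 2 - 0.05 * log2(n), noise = 0.01)
  cr <- split_and_correlate(sw, 128)
  tab <- correlation_table(list(`2` = cr, `10` = cr), parameter = "n_classes")
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("parameter", "value", "pre_r2", "post_r2",
                      "pre_kendall_tau", "post_kendall_tau",
                      "pre_spearman_rho", "post_spearman_rho"),
               ignore.order = TRUE)
})
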