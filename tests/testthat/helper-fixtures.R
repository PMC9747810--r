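# Small, fast fixtures shared across the suite. Everything is generated in
# code; sizes are kept minimal so single tests run in seconds.

tiny_spec <- function(...) {
  args <- modifyList(list(n_features = 24, n_informative = 4, n_classes = 3,
                          class_sep = 3, n_samples = 600, seed = 42),
                     list(...))
  do.call(synthetic_spec, args)
}

tiny_net <- function(input_dim = 24, n_classes = 3) {
  network_spec(input_dim, hidden_sizes = c(12, 8, 6), latent_dim = 3,
               n_classes = n_classes)
}

fast_config <- function(...) {
  do.call(train_config, modifyList(list(epochs = 15, seed = 99), list(...)))
}

# decreasing logistic on the log2(n) axis: the canonical loss-curve shape
logistic_loss <- function(x, x0 = 8, k = 1.5, lo = 1, hi = 2) {
  lo + (hi - lo) / (1 + exp(k * (x - x0)))
}

# Brute-force inflection oracle: central finite differences of the *same*
# sampled curve values, refined on the analytic function where available.
fd_argmax_d2 <- function(f, lo, hi, n_grid = 1e4, sign = 1) {
  x <- seq(lo, hi, length.out = n_grid)
  h <- x[2] - x[1]
  d2 <- (f(x + h) - 2 * f(x) + f(x - h)) / h^2
  x[which.max(sign * d2)]
}
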