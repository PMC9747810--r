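#' Specify the paired classifier / autoencoder architecture
#'
#' One spec describes both networks. The classifier `f` is a feed-forward
#' network `input_dim -> hidden_sizes[1:3] -> n_classes` with ReLU between
#' layers. The matched autoencoder `g` reuses the classifier trunk as its
#' encoder, compresses to `latent_dim` (default 3, chosen to avoid over- or
#' under-compression of the latent space), and mirrors the encoder back to
#' `input_dim` as the decoder — so the encoder has the same number of
#' hidden layers and trunk widths as the classifier.
#'
#' @param input_dim Number of input features.
#' @param hidden_sizes Exactly three positive integers: the trunk widths
#'   shared by classifier and encoder.
#' @param latent_dim Autoencoder bottleneck width; must be smaller than
#'   `input_dim`.
#' @param n_classes Number of classifier output logits (>= 2).
#' @return An object of class `mcse_network_spec`.
#' @export
network_spec <- function(input_dim, hidden_sizes = c(64, 32, 16),
                         latent_dim = 3, n_classes = 2) {
  if (length(hidden_sizes) != 3)
    abort("`hidden_sizes` must have exactly 3 entries (a 3-layer trunk)")
  hidden_sizes <- vapply(seq_along(hidden_sizes), function(i)
    check_count(hidden_sizes[i], sprintf("hidden_sizes[%d]", i)), integer(1))
  spec <- list(
    input_dim = check_count(input_dim, "input_dim"),
    hidden_sizes = hidden_sizes,
    latent_dim = check_count(latent_dim, "latent_dim"),
    n_classes = check_count(n_classes, "n_classes", min = 2L)
  )
  if (spec$latent_dim >= spec$input_dim)
    abort("`latent_dim` must be smaller than `input_dim` (compression)")
  structure(spec, class = "mcse_network_spec")
}

#' @export
print.mcse_network_spec <- function(x, ...) {
  cat(sprintf("<mcse_network_spec> f: %d -> %s -> %d | g: %d -> %s -> %d -> %s -> %d\n",
              x$input_dim, paste(x$hidden_sizes, collapse = "-"), x$n_classes,
              x$input_dim, paste(x$hidden_sizes, collapse = "-"), x$latent_dim,
              paste(rev(x$hidden_sizes), collapse = "-"), x$input_dim))
  invisible(x)
}

#' Training hyper-parameters
#'
#' @param epochs Number of passes over the training subset.
#' @param batch_size Minibatch size; training sets smaller than one batch
#'   are trained as a single reduced batch (with a warning).
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling weight initialisation and epoch
#'   shuffling; the same (data, spec, config, seed) gives identical trained
#'   parameters on one CPU thread.
#' @param early_stop_patience Stop when the held-out-validation loss has
#'   not improved for this many epochs, restoring the best weights; `0`
#'   disables early stopping (the default — fixed-epoch training keeps
#'   replicates exchangeable).
#' @return An object of class `mcse_train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 32, learning_rate = 1e-3,
                         seed = 1, early_stop_patience = 0) {
  structure(list(
    epochs = check_count(epochs, "epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = check_number(learning_rate, "learning_rate", min = 1e-12),
    seed = check_count(seed, "seed", min = -.Machine$integer.max),
    early_stop_patience = check_count(early_stop_patience,
                                      "early_stop_patience", min = 0L)
  ), class = "mcse_train_config")
}

#' @keywords internal
classifier_layers <- function(spec) {
  c(spec$input_dim, spec$hidden_sizes, spec$n_classes)
}

#' @keywords internal
autoencoder_layers <- function(spec) {
  c(spec$input_dim, spec$hidden_sizes, spec$latent_dim,
    rev(spec$hidden_sizes), spec$input_dim)
}

#' @keywords internal
count_parameters <- function(layer_sizes) {
  d <- as.numeric(layer_sizes)
  sum(d[-length(d)] * d[-1] + d[-1])
}

#' Describe the classifier network for a spec
#'
#' Returns an untrained model description (layer widths and parameter
#' count); the weights themselves are created at training time from the
#' [train_config()] seed.
#'
#' @param spec An [network_spec()].
#' @return An object of class `mcse_mlp` with fields `layer_sizes`,
#'   `type` and `n_parameters`.
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "mcse_network_spec"))
  ls <- classifier_layers(spec)
  structure(list(layer_sizes = ls, type = "classifier",
                 n_parameters = count_parameters(ls), spec = spec),
            class = "mcse_mlp")
}

#' Describe the matched autoencoder for a spec
#'
#' The encoder reuses the classifier trunk widths and compresses to
#' `latent_dim`; the decoder mirrors the encoder back to the input
#' dimension.
#'
#' @inheritParams build_classifier
#' @return An object of class `mcse_mlp`.
#' @export
build_autoencoder <- function(spec) {
  stopifnot(inherits(spec, "mcse_network_spec"))
  ls <- autoencoder_layers(spec)
  structure(list(layer_sizes = ls, type = "autoencoder",
                 n_parameters = count_parameters(ls), spec = spec),
            class = "mcse_mlp")
}

#' @export
print.mcse_mlp <- function(x, ...) {
  cat(sprintf("<mcse_mlp %s> %s (%s parameters)\n", x$type,
              paste(x$layer_sizes, collapse = " -> "),
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

# Standardise both splits with train-split statistics; constant columns get
# unit scale so they pass through unchanged.
#' @keywords internal
standardize_splits <- function(train, test) {
  mu <- colMeans(train)
  sg <- apply(train, 2, sd)
  sg[!is.finite(sg) | sg < 1e-8] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sg, "/"),
       test = sweep(sweep(test, 2, mu), 2, sg, "/"))
}

#' @keywords internal
run_training <- function(x_train, t_train, x_test, layer_sizes, softmax,
                         config) {
  if (nrow(x_train) < config$batch_size)
    warn(sprintf("training set (%d rows) smaller than batch_size (%d); using a single reduced batch",
                 nrow(x_train), config$batch_size))
  x_val <- matrix(0, 0, ncol(x_train)); t_val <- matrix(0, 0, ncol(t_train))
  if (config$early_stop_patience > 0 && nrow(x_train) >= 10) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(config$seed)
    vi <- sample(nrow(x_train), max(1L, nrow(x_train) %/% 10))
    x_val <- x_train[vi, , drop = FALSE]; t_val <- t_train[vi, , drop = FALSE]
    x_train <- x_train[-vi, , drop = FALSE]
    t_train <- t_train[-vi, , drop = FALSE]
  }
  cpp_train_mlp(x_train, t_train, x_test, as.integer(layer_sizes), softmax,
                config$epochs, config$batch_size, config$learning_rate,
                as.integer(config$seed), x_val, t_val,
                config$early_stop_patience)
}

#' Train the classifier and return its held-out macro AUC
#'
#' Fits a fresh classifier on the training rows only (features are
#' standardised with train-split statistics) and evaluates macro-averaged
#' one-vs-rest AUC on the held-out test set.
#'
#' @param train,test `mcse_dataset` tibbles (or data frames with a `label`
#'   column) sharing the same feature columns and label alphabet.
#' @param spec An [network_spec()]; defaults to one sized from the data.
#' @param config A [train_config()].
#' @return The macro one-vs-rest test AUC, a single number in `[0, 1]`.
#' @export
train_classifier <- function(train, test, spec = NULL,
                             config = train_config()) {
  xtr <- feature_matrix(train); xte <- feature_matrix(test)
  stopifnot(ncol(xtr) == ncol(xte))
  ytr <- train$label; yte <- test$label
  classes <- sort(unique(c(ytr, yte)))
  spec <- spec %||% network_spec(ncol(xtr), n_classes = length(classes))
  if (length(classes) > spec$n_classes)
    abort("more observed classes than the spec's output dimension")

  s <- standardize_splits(xtr, xte)
  onehot <- matrix(0, nrow(xtr), spec$n_classes)
  onehot[cbind(seq_len(nrow(xtr)), match(ytr, classes))] <- 1

  fit <- run_training(s$train, onehot, s$test, classifier_layers(spec),
                      softmax = TRUE, config = config)
  macro_auc(fit$predictions, match(yte, classes))
}

#' Macro one-vs-rest AUC
#'
#' Rank-based (Mann-Whitney) AUC of each class's score column against the
#' rest, averaged over classes present in `labels`. Classes with no test
#' representative are skipped with a warning.
#'
#' @param scores Numeric matrix, one column of scores per class.
#' @param labels Integer class indices (1-based column indices into
#'   `scores`).
#' @return Macro-averaged AUC in `[0, 1]`.
#' @export
macro_auc <- function(scores, labels) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  ks <- seq_len(ncol(scores))
  present <- ks %in% labels
  if (!all(present))
    warn(sprintf("%d class(es) absent from the test set; AUC averaged over the %d present",
                 sum(!present), sum(present)))
  aucs <- vapply(ks[present], function(k) {
    pos <- labels == k
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n0 == 0) return(NA_real_)
    r <- rank(scores[, k])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Train the autoencoder and return its held-out reconstruction loss
#'
#' Fits a fresh autoencoder on the training features only (standardised
#' with train-split statistics; labels are never used) and returns the mean
#' squared reconstruction error on the held-out test features.
#'
#' @param train,test Feature matrices or `mcse_dataset` tibbles with
#'   matching feature dimensionality.
#' @inheritParams train_classifier
#' @return Mean squared test reconstruction error, a non-negative number.
#' @export
train_autoencoder <- function(train, test, spec = NULL,
                              config = train_config()) {
  xtr <- feature_matrix(train); xte <- feature_matrix(test)
  stopifnot(ncol(xtr) == ncol(xte))
  spec <- spec %||% network_spec(ncol(xtr))
  if (ncol(xtr) != spec$input_dim)
    abort("feature dimensionality does not match spec$input_dim")
  s <- standardize_splits(xtr, xte)
  fit <- run_training(s$train, s$train, s$test, autoencoder_layers(spec),
                      softmax = FALSE, config = config)
  mean((fit$predictions - s$test)^2)
}
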