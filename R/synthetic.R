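#' Specify a hypercube-cluster synthetic classification dataset
#'
#' Defines the parameters of the synthetic generator used for simulation
#' studies: class centroids sit at distinct vertices of an
#' `n_informative`-dimensional hypercube with side length `class_sep`,
#' samples scatter about their centroid with unit-variance Gaussian noise,
#' and the remaining `n_features - n_informative` dimensions carry
#' class-independent standard Gaussian noise. A fraction `mislabel_rate` of
#' labels can be replaced by a uniformly random *different* class to emulate
#' imperfect annotation.
#'
#' `class_sep` is expressed in units of the within-class standard deviation
#' (which is fixed at 1), so `class_sep = 1` places neighbouring centroids
#' one within-class standard deviation apart — a deliberately hard task —
#' while `class_sep = 5` is nearly separable.
#'
#' @param n_features Total number of feature dimensions.
#' @param n_informative Number of class-informative dimensions
#'   (`<= n_features`). Classes require distinct hypercube vertices, so
#'   `n_classes <= 2^n_informative`.
#' @param n_classes Number of classes (>= 2).
#' @param class_sep Hypercube side length; positive.
#' @param n_samples Total number of samples; classes are balanced to
#'   within one sample.
#' @param mislabel_rate Fraction of labels replaced at random, in `[0, 0.5]`.
#' @param seed Integer seed; identical spec + seed gives a bitwise
#'   identical dataset.
#' @return An object of class `mcse_spec`.
#' @seealso [generate_hypercube_dataset()]
#' @export
synthetic_spec <- function(n_features = 784, n_informative = 32, n_classes = 10,
                           class_sep = 1, n_samples = 12000,
                           mislabel_rate = 0, seed = 1) {
  spec <- list(
    n_features = check_count(n_features, "n_features"),
    n_informative = check_count(n_informative, "n_informative"),
    n_classes = check_count(n_classes, "n_classes", min = 2L),
    class_sep = check_number(class_sep, "class_sep"),
    n_samples = check_count(n_samples, "n_samples"),
    mislabel_rate = check_number(mislabel_rate, "mislabel_rate", 0, 0.5),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (spec$class_sep <= 0) abort("`class_sep` must be positive")
  if (spec$n_informative > spec$n_features)
    abort("`n_informative` must not exceed `n_features`")
  if (spec$n_informative < 31 && spec$n_classes > 2^spec$n_informative)
    abort(sprintf(
      "n_classes = %d needs more hypercube vertices than the %d informative dimensions provide (2^%d = %d)",
      spec$n_classes, spec$n_informative, spec$n_informative, 2^spec$n_informative))
  structure(spec, class = "mcse_spec")
}

#' @export
print.mcse_spec <- function(x, ...) {
  cat("<mcse_spec>\n")
  cat(sprintf("  %d samples x %d features (%d informative), %d classes\n",
              x$n_samples, x$n_features, x$n_informative, x$n_classes))
  cat(sprintf("  class_sep = %g, mislabel_rate = %g, seed = %d\n",
              x$class_sep, x$mislabel_rate, x$seed))
  invisible(x)
}

# Draw K distinct vertices of the d-dimensional hypercube, uniformly at
# random from the 2^d available, using the caller's RNG stream. Random
# placement keeps every informative dimension class-relevant in
# expectation, so n_informative is a meaningful difficulty axis.
#' @keywords internal
sample_vertices <- function(K, d) {
  if (d <= 25) {
    codes <- sample.int(2^d, K) - 1L
    bits <- t(vapply(codes, function(g)
      as.integer(bitwAnd(bitwShiftR(g, seq_len(d) - 1L), 1L)), integer(d)))
    return(bits)
  }
  # large d: rejection-free in practice (collision probability ~ K^2 / 2^d)
  repeat {
    bits <- matrix(sample(0:1, K * d, replace = TRUE), K, d)
    if (!anyDuplicated(bits)) return(bits)
  }
}

#' Generate a hypercube-cluster classification dataset
#'
#' Draws the dataset described by a [synthetic_spec()]: each class is
#' centred on a distinct, randomly chosen vertex of the
#' informative-dimensional hypercube (seeded, so reproducible),
#' informative coordinates get unit-variance Gaussian scatter, the
#' remaining coordinates are pure standard Gaussian noise, class counts are
#' balanced to within one sample, and `mislabel_rate` of the labels are
#' then replaced by a random different class.
#'
#' @param spec An [synthetic_spec()] object.
#' @return A tibble of class `mcse_dataset` with feature columns
#'   `f1...f<n_features>`, an integer `label` column in `0...n_classes-1`,
#'   and a `true_label` column holding the pre-noise labels. The generating
#'   spec is attached as attribute `"spec"`.
#' @examples
#' d <- generate_hypercube_dataset(synthetic_spec(
#'   n_features = 20, n_informative = 4, n_classes = 3,
#'   n_samples = 90, seed = 7))
#' table(d$label)
#' @export
generate_hypercube_dataset <- function(spec) {
  stopifnot(inherits(spec, "mcse_spec"))
  n <- spec$n_samples; p <- spec$n_features
  d <- spec$n_informative; K <- spec$n_classes

  # balanced to within +/-1: remainder goes to the lowest class indices
  counts <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  labels <- rep.int(seq_len(K) - 1L, counts)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  centroids <- sample_vertices(K, d) * spec$class_sep
  x <- matrix(rnorm(n * p), n, p)
  x[, seq_len(d)] <- x[, seq_len(d)] + centroids[labels + 1L, , drop = FALSE]

  ord <- sample.int(n) # shuffle so class blocks do not survive subsetting
  x <- x[ord, , drop = FALSE]
  labels <- labels[ord]

  colnames(x) <- paste0("f", seq_len(p))
  out <- as_tibble(x)
  out$label <- labels
  out$true_label <- labels
  out <- new_mcse_dataset(out, spec)
  if (spec$mislabel_rate > 0) {
    out <- mislabel(out, spec$mislabel_rate, seed = spec$seed + 1L)
  }
  out
}

#' @keywords internal
new_mcse_dataset <- function(tbl, spec = NULL) {
  structure(tbl, spec = spec, class = c("mcse_dataset", class(tibble())))
}

# save/restore .Random.seed so generators do not disturb the caller's RNG
#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
#' @keywords internal
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Randomly corrupt a fraction of labels
#'
#' Each sample independently has its label replaced with probability
#' `rate`; the replacement is drawn uniformly from the *other* classes, so
#' a corrupted label is never the original one. `true_label` is preserved
#' for diagnostics.
#'
#' @param dataset An `mcse_dataset` (any data frame with `label` and
#'   `true_label` columns).
#' @param rate Corruption probability per sample, in `[0, 0.5]`.
#' @param seed Integer seed for the corruption draw.
#' @return The dataset with its `label` column corrupted.
#' @export
mislabel <- function(dataset, rate, seed = 1) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset))
  rate <- check_number(rate, "rate", 0, 0.5)
  if (rate == 0) return(dataset)
  classes <- sort(unique(dataset$true_label %||% dataset$label))
  K <- length(classes)
  if (K < 2) abort("cannot mislabel a dataset with fewer than 2 classes")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- nrow(dataset)
  hit <- runif(n) < rate
  if (any(hit)) {
    # shift by 1..K-1 classes: uniform over the K-1 *different* classes
    cur <- match(dataset$label[hit], classes) - 1L
    shift <- sample.int(K - 1L, sum(hit), replace = TRUE)
    dataset$label[hit] <- classes[((cur + shift) %% K) + 1L]
  }
  dataset
}

#' Read a delimited feature matrix (optionally labeled) from disk
#'
#' Parses a comma-delimited text file with samples in rows. When
#' `has_labels = TRUE` the final column is taken as an integer class label
#' and re-indexed to `0...K-1` in sorted order of the observed values.
#'
#' @param path Path to a CSV file.
#' @param has_labels Does the final column hold class labels?
#' @param header Does the file start with a header row?
#' @return An `mcse_dataset` tibble (with `label`/`true_label` when
#'   `has_labels`), or a plain feature tibble otherwise.
#' @export
load_csv_dataset <- function(path, has_labels = FALSE, header = TRUE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  # base read.csv: strtod parsing round-trips written doubles bitwise
  tbl <- tryCatch(
    utils::read.csv(path, header = header, fill = FALSE),
    error = function(e) abort(sprintf("malformed CSV: %s",
                                      conditionMessage(e))),
    warning = function(w) abort(sprintf("malformed CSV: %s",
                                        conditionMessage(w))))
  tbl <- as_tibble(tbl)
  if (!header) names(tbl) <- paste0("f", seq_along(tbl))
  bad <- names(tbl)[!vapply(tbl, is.numeric, logical(1))]
  if (length(bad) > 0)
    abort(sprintf("non-numeric cells in column(s): %s",
                  paste(bad, collapse = ", ")))
  if (anyNA(tbl)) abort("dataset contains missing values")

  if (!has_labels) return(as_tibble(tbl))
  if (ncol(tbl) < 2) abort("labeled dataset needs at least one feature column")
  raw <- tbl[[ncol(tbl)]]
  if (any(raw != round(raw))) abort("label column must be integer-valued")
  classes <- sort(unique(raw))
  if (length(classes) < 2)
    abort("label column has fewer than 2 classes")
  out <- tbl[-ncol(tbl)]
  names(out) <- paste0("f", seq_along(out))
  out$label <- match(raw, classes) - 1L
  out$true_label <- out$label
  new_mcse_dataset(out)
}

#' Write a dataset to CSV
#'
#' Writes features followed by the label column (when present) using
#' round-trippable numeric formatting, so
#' `load_csv_dataset(write_csv_dataset(d, f), has_labels = TRUE)`
#' reproduces `d` bitwise.
#'
#' @param dataset An `mcse_dataset` or feature data frame.
#' @param path Output path.
#' @param labels Include the label column (if present)?
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(dataset, path, labels = "label" %in% names(dataset)) {
  out <- as_tibble(dataset)
  out$true_label <- NULL
  if (!labels) out$label <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.mcse_dataset <- function(x, ...) {
  spec <- attr(x, "spec")
  p <- sum(!names(x) %in% c("label", "true_label"))
  cat(sprintf("<mcse_dataset> %d samples x %d features", nrow(x), p))
  if ("label" %in% names(x))
    cat(sprintf(", %d classes", length(unique(x$label))))
  cat("\n")
  if (!is.null(spec)) print(spec)
  NextMethod()
}
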