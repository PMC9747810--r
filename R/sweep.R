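#' Define the bootstrapped sample-size sweep
#'
#' The sweep trains a fresh classifier/autoencoder pair at each sample size
#' in a doubling schedule, `n_bootstrap` times per size, always evaluating
#' on one fixed held-out test split. Defaults mirror the canonical design:
#' sizes 16, 32, 64, ... doubling up to the training pool (the final entry
#' is the full pool when it is not itself a power of two), 50 bootstrap
#' replicates, and a test split of 10,000 samples or 20% of the data,
#' whichever is smaller.
#'
#' @param sample_sizes Strictly increasing positive integers, or `NULL` to
#'   derive the doubling schedule from the pool at run time.
#' @param n_bootstrap Replicates per sample size.
#' @param test_size Held-out test rows, or `NULL` for
#'   `min(10000, 20% of data)`.
#' @param base_seed Integer master seed; every subsample draw and training
#'   run derives its own seed from `(base_seed, size index, replicate)`.
#' @return An object of class `mcse_schedule`.
#' @export
sweep_schedule <- function(sample_sizes = NULL, n_bootstrap = 50,
                           test_size = NULL, base_seed = 1) {
  if (!is.null(sample_sizes)) {
    sample_sizes <- vapply(seq_along(sample_sizes), function(i)
      check_count(sample_sizes[i], "sample_sizes"), integer(1))
    if (any(diff(sample_sizes) <= 0))
      abort("`sample_sizes` must be strictly increasing")
  }
  structure(list(
    sample_sizes = sample_sizes,
    n_bootstrap = check_count(n_bootstrap, "n_bootstrap"),
    test_size = if (!is.null(test_size)) check_count(test_size, "test_size"),
    base_seed = check_count(base_seed, "base_seed", min = -.Machine$integer.max)
  ), class = "mcse_schedule")
}

# Fill in data-dependent defaults: test split size, then the doubling
# schedule truncated to the remaining pool with the full pool appended.
#' @keywords internal
resolve_schedule <- function(schedule, n_total, min_size = 16L) {
  test_size <- schedule$test_size %||% min(10000L, floor(0.2 * n_total))
  pool <- n_total - test_size
  sizes <- schedule$sample_sizes
  if (is.null(sizes)) {
    sizes <- min_size * 2^(0:floor(log2(pool / min_size)))
    if (tail(sizes, 1) < pool) sizes <- c(sizes, pool)
    sizes <- as.integer(sizes)
  }
  if (max(sizes) > pool)
    abort(sprintf(
      "insufficient data: max sample size %d needs a pool of %d + test split of %d = %d rows, have %d",
      max(sizes), max(sizes), test_size, max(sizes) + test_size, n_total),
      class = "mcse_insufficient_data")
  schedule$sample_sizes <- sizes
  schedule$test_size <- as.integer(test_size)
  schedule
}

#' @export
print.mcse_schedule <- function(x, ...) {
  sz <- if (is.null(x$sample_sizes)) "doubling (resolved at run time)"
        else paste(x$sample_sizes, collapse = ", ")
  cat(sprintf("<mcse_schedule> sizes: %s\n  %d bootstrap replicates, test_size = %s, base_seed = %d\n",
              sz, x$n_bootstrap, x$test_size %||% "auto", x$base_seed))
  invisible(x)
}

#' Run the bootstrapped sample-size sweep
#'
#' For every sample size `n` and replicate `r`, draws `n` rows without
#' replacement from the training pool (the data minus one fixed held-out
#' test split), trains a fresh classifier on the labeled draw and a fresh
#' autoencoder on the same draw's features, and records held-out macro AUC
#' and reconstruction loss. Classifier and autoencoder share the draw, so
#' the two learning curves are paired. Every draw and training run is
#' seeded from `(base_seed, size index, replicate)`, making the sweep fully
#' reproducible and each `(n, r)` cell independent of the others.
#'
#' @param dataset An `mcse_dataset` (or data frame with a `label` column).
#' @param schedule An [sweep_schedule()].
#' @param net_spec An [network_spec()]; defaults to one sized from the
#'   data with the standard trunk.
#' @param config A [train_config()]; its `seed` field is overridden by
#'   the derived per-replicate seeds.
#' @param metrics Which learning curves to record: `"auc"` (classifier),
#'   `"loss"` (autoencoder), or both (default). The MCSE itself only needs
#'   `"loss"`; `"auc"` is required for the correlation and extrapolation
#'   stages.
#' @param completed Optional data frame of already-computed records (e.g. a
#'   previously written sweep CSV) with at least `n` and `replicate`
#'   columns; matching `(n, replicate)` cells are skipped and the rows
#'   reused, so an interrupted sweep can be resumed to an identical result.
#' @param progress Print a line per (n, replicate) to stderr?
#' @return A tibble of class `mcse_sweep` with columns `n`, `replicate`,
#'   `seed`, `auc`, `loss` (one row per `(n, replicate)`), carrying the
#'   resolved schedule, network spec, train config, dataset fingerprint and
#'   test-split indices as attributes.
#' @export
run_sweep <- function(dataset, schedule = sweep_schedule(), net_spec = NULL,
                      config = train_config(), metrics = c("auc", "loss"),
                      completed = NULL, progress = FALSE) {
  stopifnot(is.data.frame(dataset))
  metrics <- match.arg(metrics, several.ok = TRUE)
  want_auc <- "auc" %in% metrics
  if (want_auc && !"label" %in% names(dataset))
    abort("dataset has no `label` column; use metrics = \"loss\"")

  n_total <- nrow(dataset)
  schedule <- resolve_schedule(schedule, n_total)

  x <- feature_matrix(dataset)
  labels <- if ("label" %in% names(dataset)) dataset$label
  classes <- if (!is.null(labels)) sort(unique(labels))
  net_spec <- net_spec %||%
    network_spec(ncol(x), n_classes = max(2L, length(classes)))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(schedule$base_seed)
  test_idx <- sort(sample.int(n_total, schedule$test_size))
  pool_idx <- setdiff(seq_len(n_total), test_idx)

  test_x <- x[test_idx, , drop = FALSE]
  test_df <- dataset[test_idx, , drop = FALSE]

  done <- if (!is.null(completed) && nrow(completed) > 0) {
    paste(completed$n, completed$replicate)
  } else character(0)

  grid <- tidyr::expand_grid(
    size_index = seq_along(schedule$sample_sizes),
    replicate = seq_len(schedule$n_bootstrap)
  )
  records <- purrr::pmap(grid, function(size_index, replicate) {
    n <- schedule$sample_sizes[size_index]
    key <- paste(n, replicate)
    if (key %in% done) {
      row <- completed[paste(completed$n, completed$replicate) == key, ][1, ]
      return(tibble(n = n, replicate = replicate, seed = row$seed,
                    auc = row$auc %||% NA_real_,
                    loss = row$loss %||% NA_real_))
    }
    seed_nr <- derive_seed(schedule$base_seed, size_index, replicate)
    set.seed(seed_nr)
    draw <- pool_idx[sample.int(length(pool_idx), n)]
    cfg <- config
    cfg$seed <- seed_nr
    if (progress)
      message(sprintf("sweep: n = %d, replicate = %d (seed %d)",
                      n, replicate, seed_nr))
    auc <- if (want_auc)
      train_classifier(dataset[draw, , drop = FALSE], test_df,
                       spec = net_spec, config = cfg) else NA_real_
    loss <- if ("loss" %in% metrics)
      train_autoencoder(x[draw, , drop = FALSE], test_x,
                        spec = net_spec, config = cfg) else NA_real_
    tibble(n = n, replicate = replicate, seed = seed_nr,
           auc = auc, loss = loss)
  })
  out <- dplyr::bind_rows(records)
  structure(out,
            schedule = schedule, net_spec = net_spec, train_config = config,
            metrics = metrics,
            fingerprint = rlang::hash(list(x, labels)),
            spec = attr(dataset, "spec"),
            test_idx = test_idx,
            class = c("mcse_sweep", class(tibble())))
}

#' Summarise a sweep per sample size
#'
#' @param sweep An `mcse_sweep` (or any data frame with `n`, `auc`, `loss`
#'   columns).
#' @return A tibble with one row per sample size, ordered by `n`: replicate
#'   count, mean and standard deviation of AUC and loss (single-replicate
#'   standard deviations are reported as 0).
#' @export
aggregate_sweep <- function(sweep) {
  stopifnot(is.data.frame(sweep), all(c("n", "auc", "loss") %in% names(sweep)))
  sd0 <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(if (length(v)) 0 else NA_real_)
    sd(v)
  }
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  sweep |>
    as_tibble() |>
    dplyr::group_by(n = .data$n) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      auc_mean = mean_na(.data$auc), auc_sd = sd0(.data$auc),
      loss_mean = mean_na(.data$loss), loss_sd = sd0(.data$loss),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$n)
}

#' Write / read sweep records as tidy CSV with a JSON sidecar
#'
#' The CSV holds one row per `(n, replicate)` with columns
#' `n, replicate, seed, auc, loss`; the sidecar
#' (`<path>.meta.json`) echoes the resolved schedule, network spec, train
#' config and dataset fingerprint, which is enough to reproduce the sweep.
#'
#' @param sweep An `mcse_sweep`.
#' @param path CSV output path.
#' @return `path`, invisibly (`write_sweep_csv`); an `mcse_sweep` tibble
#'   (`read_sweep_csv`).
#' @export
write_sweep_csv <- function(sweep, path) {
  readr::write_csv(as_tibble(sweep), path, progress = FALSE)
  meta <- list(
    package_version = as.character(utils::packageVersion("mcse")),
    schedule = unclass(attr(sweep, "schedule")),
    net_spec = unclass(attr(sweep, "net_spec")),
    train_config = unclass(attr(sweep, "train_config")),
    metrics = attr(sweep, "metrics"),
    fingerprint = attr(sweep, "fingerprint"),
    dataset_spec = if (!is.null(attr(sweep, "spec"))) unclass(attr(sweep, "spec"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta_path <- paste0(path, ".meta.json")
  atts <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  structure(tbl,
            schedule = atts$schedule, net_spec = atts$net_spec,
            train_config = atts$train_config, metrics = atts$metrics,
            fingerprint = atts$fingerprint, spec = atts$dataset_spec,
            class = c("mcse_sweep", class(tibble())))
}

#' @export
print.mcse_sweep <- function(x, ...) {
  sch <- attr(x, "schedule")
  cat(sprintf("<mcse_sweep> %d records: %d sample sizes x %s replicates\n",
              nrow(x), length(unique(x$n)),
              if (!is.null(sch)) sch$n_bootstrap else "?"))
  NextMethod()
}
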