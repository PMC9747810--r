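#' @keywords internal
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, deparse(substitute(x))))
  }
  as.integer(x)
}

#' @keywords internal
check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  as.numeric(x)
}

# Injective over (size_index, replicate) for replicate counts below 100003;
# kept well under 2^31 so it is a valid R integer seed.
#' @keywords internal
derive_seed <- function(base_seed, size_index, replicate) {
  (abs(as.integer(base_seed)) + 100003 * (size_index - 1L) + replicate) %% 2147483629L
}

#' Extract the feature matrix from a dataset
#'
#' Returns the numeric feature columns of an `mcse_dataset` (or any data
#' frame) as a plain matrix, dropping the `label`/`true_label` columns when
#' present. Matrices are passed through unchanged.
#'
#' @param data A data frame or matrix of features.
#' @return A numeric matrix, samples in rows.
#' @export
feature_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  stopifnot(is.data.frame(data))
  keep <- setdiff(names(data), c("label", "true_label"))
  m <- as.matrix(data[keep])
  if (!is.numeric(m)) abort("feature columns must all be numeric")
  m
}
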