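# internal helpers shared across modules

#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
NULL

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# row-wise span (max - min over non-missing entries) of a numeric matrix,
# NA where a row has < 2 observed values
row_span <- function(mat) {
  cols <- lapply(seq_len(ncol(mat)), function(j) mat[, j])
  n_obs <- rowSums(!is.na(mat))
  hi <- suppressWarnings(do.call(pmax, c(cols, list(na.rm = TRUE))))
  lo <- suppressWarnings(do.call(pmin, c(cols, list(na.rm = TRUE))))
  out <- hi - lo
  out[n_obs < 2] <- NA_real_
  out
}

assert_scalar_prob <- function(x, name, lo = 0, hi = 1,
                               lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s, got %s",
                  name, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]",
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}
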