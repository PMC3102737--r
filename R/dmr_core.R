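# Core DMR machinery: per-sample / group-average methylation profiles,
# threshold-based differential calls, and global methylation summaries.
#
# A DMR here is a single CpG probe whose beta value differs by >= theta
# (default 0.3) between two profiles; the comparison is inclusive at the
# boundary. There is no statistical test: the definition is a pure threshold
# on the group difference.

#' Construct a methylation profile
#'
#' A profile is a per-probe beta vector for one sample or one group of
#' samples: a tibble with `probe_id`, `beta` (NA = missing/excluded) and
#' `n_members` (number of samples contributing at each probe).
#'
#' @param probe_id Character probe ids.
#' @param beta Numeric beta values in \[0, 1\] or NA.
#' @param n_members Integer contributions per probe.
#' @param label Profile name.
#' @return A `methylation_profile` tibble.
#' @export
methylation_profile <- function(probe_id, beta, n_members = 1L, label = "profile") {
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad)) abort(sprintf("beta out of [0, 1] at probe '%s'", probe_id[bad[1]]))
  structure(tibble(probe_id = as.character(probe_id),
                   beta = as.numeric(beta),
                   n_members = as.integer(n_members)),
            label = label,
            class = c("methylation_profile", class(tibble())))
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("# methylation_profile '%s': %d probes (%d missing)\n",
              attr(x, "label"), nrow(x), sum(is.na(x$beta))))
  NextMethod()
}

#' Profile of a single sample
#'
#' @param x A [beta_matrix()].
#' @param sample One sample id present in `x`.
#' @param label Profile label; defaults to the sample id.
#' @return A [methylation_profile()].
#' @export
sample_profile <- function(x, sample, label = sample) {
  stopifnot(inherits(x, "beta_matrix"))
  if (!sample %in% sample_ids(x)) abort(sprintf("sample '%s' not in beta matrix", sample))
  b <- x[[sample]]
  methylation_profile(x$probe_id, b, n_members = as.integer(!is.na(b)), label = label)
}

#' Group-average methylation profile with intra-group DMR exclusion
#'
#' Averages beta values over the member samples. With
#' `intra_exclude = TRUE` (the default, matching how group references are
#' built for ESC/iPSC/parent comparisons), any probe at which some pair of
#' members differs by `>= theta` is set to missing in the group profile, so
#' it is excluded from every downstream comparison involving this group --
#' but only for this group; the global probe universe is untouched.
#'
#' With `require_complete = TRUE` (default) a probe masked in any member is
#' also set to missing, so comparisons never mix member subsets; set it to
#' `FALSE` to average over the unmasked members instead.
#'
#' @param x A [beta_matrix()].
#' @param members Non-empty character vector of sample ids in `x`.
#' @param intra_exclude Drop probes with intra-group differences >= `theta`?
#' @param theta Intra-group exclusion threshold (same scale as DMR calls).
#' @param require_complete Treat probes masked in any member as missing?
#' @param label Profile label.
#' @return A [methylation_profile()].
#' @export
group_average <- function(x, members, intra_exclude = TRUE, theta = 0.3,
                          require_complete = TRUE, label = "group") {
  stopifnot(inherits(x, "beta_matrix"))
  if (!length(members)) abort("empty member set")
  miss <- setdiff(members, sample_ids(x))
  if (length(miss)) abort(paste("members not in beta matrix:", paste(miss, collapse = ", ")))
  assert_scalar_prob(theta, "theta", lo_open = TRUE)
  m <- beta_values(x)[, members, drop = FALSE]
  n_obs <- rowSums(!is.na(m))
  beta <- rowMeans(m, na.rm = TRUE)
  beta[n_obs == 0] <- NA_real_
  if (require_complete) beta[n_obs < length(members)] <- NA_real_
  if (intra_exclude && length(members) >= 2) {
    span <- row_span(m)
    beta[!is.na(span) & span >= theta] <- NA_real_
  }
  methylation_profile(x$probe_id, beta,
                      n_members = ifelse(is.na(beta), 0L, n_obs),
                      label = label)
}

#' Call DMRs between two methylation profiles
#'
#' A probe is called when both profiles are non-missing there and the beta
#' difference is `>= theta` in absolute value ("0.3 points or more";
#' inclusive boundary). Direction is `hyper` when the first profile is the
#' higher one. The two profiles must share a probe universe.
#'
#' @param a,b [methylation_profile()]s on a shared probe universe.
#' @param theta Calling threshold in (0, 1\]; default 0.3.
#' @return A `dmr_calls` tibble: `probe_id`, `beta_a`, `beta_b`, `delta`
#'   (`beta_a - beta_b`), `direction`. Attributes carry `theta`, both labels
#'   and the shared probe universe.
#' @export
call_dmrs <- function(a, b, theta = 0.3) {
  stopifnot(inherits(a, "methylation_profile"), inherits(b, "methylation_profile"))
  assert_scalar_prob(theta, "theta", lo_open = TRUE)
  universe <- intersect(a$probe_id, b$probe_id)
  if (!length(universe)) abort("profiles share no probes")
  av <- a$beta[match(universe, a$probe_id)]
  bv <- b$beta[match(universe, b$probe_id)]
  delta <- av - bv
  called <- !is.na(delta) & abs(delta) >= theta
  dd <- delta[called]
  structure(tibble(probe_id = universe[called],
                   beta_a = av[called],
                   beta_b = bv[called],
                   delta = dd,
                   direction = dplyr::if_else(dd > 0, "hyper", "hypo")),
            theta = theta,
            label_a = attr(a, "label"),
            label_b = attr(b, "label"),
            universe = universe,
            class = c("dmr_calls", class(tibble())))
}

#' @export
print.dmr_calls <- function(x, ...) {
  cat(sprintf("# dmr_calls: %d sites ('%s' vs '%s', theta = %g; universe %d probes)\n",
              nrow(x), attr(x, "label_a") %||% "a", attr(x, "label_b") %||% "b",
              attr(x, "theta"), length(attr(x, "universe"))))
  NextMethod()
}

#' Count highly methylated probes
#'
#' Number of non-missing probes with beta strictly greater than `cut`
#' (default 0.6, the conventional "high methylation" cut).
#'
#' @param p A [methylation_profile()].
#' @param cut Threshold in (0, 1); strict comparison.
#' @return Integer count.
#' @export
high_methylation_count <- function(p, cut = 0.6) {
  stopifnot(inherits(p, "methylation_profile"))
  assert_scalar_prob(cut, "cut", lo_open = TRUE, hi_open = TRUE)
  sum(p$beta > cut, na.rm = TRUE)
}

#' Histogram of beta values
#'
#' Bins the non-missing probe betas of a profile into `bins` equal-width bins
#' on \[0, 1\]; bins are half-open `[lo, hi)` except the last, which is
#' closed so that beta = 1 is counted.
#'
#' @param p A [methylation_profile()].
#' @param bins Number of bins (>= 2).
#' @return Tibble `bin`, `lo`, `hi`, `count`; counts sum to the number of
#'   non-missing probes.
#' @export
beta_distribution <- function(p, bins = 20L) {
  stopifnot(inherits(p, "methylation_profile"))
  if (!is.numeric(bins) || length(bins) != 1 || bins < 2) abort("`bins` must be >= 2")
  bins <- as.integer(bins)
  b <- p$beta[!is.na(p$beta)]
  breaks <- (0:bins) / bins
  idx <- findInterval(b, breaks, rightmost.closed = TRUE)
  tibble(bin = seq_len(bins),
         lo = breaks[-length(breaks)],
         hi = breaks[-1],
         count = as.integer(tabulate(idx, nbins = bins)))
}

#' Write a DMR call set as TSV, annotated
#'
#' @param calls A `dmr_calls` tibble from [call_dmrs()].
#' @param ann Probe annotation tibble ([read_probe_annotation()]).
#' @param path Output TSV.
#' @export
write_dmr_calls <- function(calls, ann, path) {
  out <- dplyr::left_join(calls, ann, by = "probe_id")
  out <- dplyr::select(out, "probe_id", "gene_symbol", "chromosome",
                       "cpg_island", "beta_a", "beta_b", "delta", "direction")
  readr::write_tsv(dplyr::arrange(out, .data$probe_id), path, progress = FALSE)
  invisible(path)
}
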