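# Passage-series tracking of ES-iPS-DMRs for one line: cohorts by passage of
# first appearance, survival, convergence summaries, difference-value
# profiles, parent-line drift and the imprinted-locus screen.
#
# "Appearance" is observational at the sampled passages: no interpolation
# between them. The inherited/aberrant class of a site is recomputed at each
# passage (inherited sites can behave like aberrant ones over time).

#' Build passage cohorts of ES-iPS-DMRs for one line
#'
#' Assigns every probe ever called in the series to the cohort of the first
#' passage at which it is called, and records per (probe, passage) whether
#' it is still called and its class there. The de novo count at a later
#' passage p is the size of cohort(p).
#'
#' @param series List of `es_ips_dmrs` (from [call_es_ips_dmrs()]) for one
#'   line, each carrying its `passage` attribute. At least two passages,
#'   strictly increasing and duplicate-free.
#' @return A `cohort_track` tibble: `probe_id`, `first_passage`, `passage`,
#'   `called`, `class`, `delta` -- one row per ever-called probe per
#'   observation passage. Attributes: `line`, `passages`.
#' @export
build_cohorts <- function(series) {
  if (length(series) < 2) abort("need >= 2 passages to build cohorts")
  passages <- vapply(series, function(s) as.integer(attr(s, "passage")), integer(1))
  if (anyNA(passages)) abort("every call set needs a passage attribute")
  if (anyDuplicated(passages)) abort("duplicate passages in series")
  if (is.unsorted(passages, strictly = TRUE)) abort("passages must be strictly increasing")
  lines <- unique(vapply(series, function(s) attr(s, "line") %||% NA_character_, character(1)))
  if (length(lines) > 1) abort("series mixes multiple lines")
  long <- purrr::map2_dfr(series, passages, function(s, p) {
    dplyr::mutate(dplyr::select(as_tibble(s), "probe_id", "class", "delta"),
                  passage = p)
  })
  if (nrow(long) == 0) {
    empty <- tibble(probe_id = character(), first_passage = integer(),
                    passage = integer(), called = logical(),
                    class = character(), delta = numeric())
    return(structure(empty, line = lines, passages = passages,
                     class = c("cohort_track", class(tibble()))))
  }
  first_at <- long |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(first_passage = min(.data$passage), .groups = "drop")
  grid <- tidyr::expand_grid(probe_id = first_at$probe_id, passage = passages) |>
    dplyr::left_join(first_at, by = "probe_id") |>
    dplyr::left_join(long, by = c("probe_id", "passage")) |>
    dplyr::mutate(called = !is.na(.data$class)) |>
    dplyr::select("probe_id", "first_passage", "passage", "called", "class", "delta") |>
    dplyr::arrange(.data$probe_id, .data$passage)
  structure(grid,
            line = lines,
            passages = passages,
            class = c("cohort_track", class(tibble())))
}

#' @export
print.cohort_track <- function(x, ...) {
  cat(sprintf("# cohort_track: line '%s', passages %s, %d ever-called probes\n",
              attr(x, "line") %||% "?",
              paste0("P", attr(x, "passages"), collapse = ", "),
              dplyr::n_distinct(x$probe_id)))
  NextMethod()
}

# survival(p, q): members of cohort(p) still called at passage q
cohort_survival <- function(track, p, q) {
  rows <- track[track$first_passage == p & track$passage == q & track$called, ]
  rows$probe_id
}

#' Per-passage totals, de novo counts and convergence flags
#'
#' @param track A [build_cohorts()] result.
#' @return Tibble `passage`, `total` (called sites), `de_novo` (cohort size;
#'   `NA` at the first passage, where appearance cannot be distinguished
#'   from presence since derivation), `surviving_initial` (members of the
#'   first cohort still called). Attribute `flags` (also via
#'   [generics::glance()]): `decreasing_total` -- total at the last passage
#'   is below the first; `de_novo_nonincreasing` -- de novo counts never
#'   increase across the later passages.
#' @export
convergence_summary <- function(track) {
  stopifnot(inherits(track, "cohort_track"))
  passages <- attr(track, "passages")
  p1 <- passages[1]
  per <- purrr::map_dfr(passages, function(p) {
    called <- track[track$passage == p & track$called, ]
    tibble(passage = p,
           total = nrow(called),
           de_novo = if (p == p1) NA_integer_ else sum(called$first_passage == p &
                                                         called$passage == p),
           surviving_initial = sum(called$first_passage == p1))
  })
  # de novo at p counts cohort(p) at its own passage (all called by definition)
  dn <- per$de_novo[-1]
  flags <- list(decreasing_total = per$total[nrow(per)] < per$total[1],
                de_novo_nonincreasing = length(dn) < 2 || all(diff(dn) <= 0))
  structure(per, flags = flags, line = attr(track, "line"),
            class = c("convergence_summary", class(tibble())))
}

#' Difference-value profile of a probe set across passages
#'
#' The difference value of a probe is `beta_sample - beta_esc` (in
#' \[-1, 1\]); positive means hyper-methylated relative to the ESC average.
#'
#' @param series Named list of [methylation_profile()]s, one per passage,
#'   names coercible to the passage numbers.
#' @param esc_avg ESC group-average [methylation_profile()].
#' @param probes Character vector of probe ids (within the shared universe).
#' @return A `difference_profile` tibble `probe_id`, `passage`, `delta`.
#' @export
difference_profile <- function(series, esc_avg, probes) {
  passages <- as.integer(names(series))
  if (anyNA(passages)) abort("`series` must be named by passage number")
  miss <- setdiff(probes, esc_avg$probe_id)
  if (length(miss)) abort(sprintf("%d probe(s) outside the universe (first: %s)",
                                  length(miss), miss[1]))
  esc <- esc_avg$beta[match(probes, esc_avg$probe_id)]
  out <- purrr::map2_dfr(series, passages, function(prof, p) {
    tibble(probe_id = probes,
           passage = p,
           delta = prof$beta[match(probes, prof$probe_id)] - esc)
  })
  structure(dplyr::arrange(out, .data$passage, .data$probe_id),
            class = c("difference_profile", class(tibble())))
}

#' Per-passage summary of a difference profile
#'
#' Mean absolute difference value is the headline convergence metric (signed
#' means would let hyper and hypo deviations cancel); the fraction of
#' positive differences measures the hyper-methylation bias.
#'
#' @param dp A [difference_profile()] result.
#' @return Tibble `passage`, `mean_abs_delta`, `frac_positive`, `n`.
#' @export
difference_summary <- function(dp) {
  dp |>
    dplyr::filter(!is.na(.data$delta)) |>
    dplyr::group_by(.data$passage) |>
    dplyr::summarise(mean_abs_delta = mean(abs(.data$delta)),
                     frac_positive = mean(.data$delta > 0),
                     n = dplyr::n(),
                     .groups = "drop")
}

#' Passage drift of a parent line relative to the ESC average
#'
#' Applies the cohort machinery to a parent line's passage series: DMRs vs
#' the ESC average are called at each passage (no inherited/aberrant split
#' -- there is no grandparent) and cohorted by first appearance. In contrast
#' to iPSC lines, parental de novo sites do not decay: the summary carries a
#' `nondecreasing_total` flag for that contrast.
#'
#' @param series Named list of parent [methylation_profile()]s, one per
#'   passage (>= 2), names coercible to passage numbers.
#' @param esc_avg ESC group-average [methylation_profile()].
#' @param theta Calling threshold; default 0.3.
#' @param line_name Parent line name for the report.
#' @return A [convergence_summary()] tibble with an additional
#'   `nondecreasing_total` flag in its `flags` attribute.
#' @export
parent_drift <- function(series, esc_avg, theta = 0.3, line_name = "parent") {
  if (length(series) < 2) abort("need >= 2 passages for parent drift")
  passages <- as.integer(names(series))
  if (anyNA(passages)) abort("`series` must be named by passage number")
  sets <- purrr::map2(series, passages, function(prof, p) {
    call_es_ips_dmrs(prof, esc_avg, parent = NULL, theta = theta,
                     line_name = line_name, passage = p)
  })
  summ <- convergence_summary(build_cohorts(sets))
  flags <- attr(summ, "flags")
  flags$nondecreasing_total <- all(diff(summ$total) >= 0)
  attr(summ, "flags") <- flags
  summ
}

#' Screen imprinted loci for aberrant methylation
#'
#' Imprinted differentially methylated regions are expected near 50%
#' methylation (one methylated parental allele). A line/locus is `normal`
#' when `|beta - expected| < theta_imprint`, otherwise `hyper-aberrant` or
#' `hypo-aberrant` by sign; loci absent from a profile are `unmeasured`.
#'
#' @param profiles Named list of [methylation_profile()]s, one per line.
#' @param loci Tibble with `probe_id` and optional `expected` (default 0.5)
#'   and `locus` (label) columns.
#' @param theta_imprint Aberrance threshold; defaults to the main DMR
#'   threshold 0.3.
#' @return Tibble `line`, `locus`, `probe_id`, `beta`, `expected`, `status`.
#' @export
imprint_report <- function(profiles, loci, theta_imprint = 0.3) {
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    abort("`profiles` must be a named list (one profile per line)")
  }
  loci <- as_tibble(loci)
  if (!"expected" %in% names(loci)) loci$expected <- 0.5
  if (!"locus" %in% names(loci)) loci$locus <- loci$probe_id
  purrr::imap_dfr(profiles, function(prof, line) {
    beta <- prof$beta[match(loci$probe_id, prof$probe_id)]
    measured <- loci$probe_id %in% prof$probe_id & !is.na(beta)
    dev <- beta - loci$expected
    tibble(line = line,
           locus = loci$locus,
           probe_id = loci$probe_id,
           beta = beta,
           expected = loci$expected,
           status = dplyr::case_when(
             !measured ~ "unmeasured",
             abs(dev) < theta_imprint ~ "normal",
             dev > 0 ~ "hyper-aberrant",
             TRUE ~ "hypo-aberrant"
           ))
  }) |>
    dplyr::arrange(.data$line, .data$locus)
}
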