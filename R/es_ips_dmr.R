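# Per-iPSC-line differences from the ESC group average ("ES-iPS-DMRs"),
# decomposed into parent-inherited vs aberrant sites, with cross-line
# overlap spectra and chromosome / island / sex stratification.

#' Call ES-iPS-DMRs for one iPSC line and classify them
#'
#' A probe is called when the line's beta differs from the ESC group average
#' by `>= theta` (both non-missing). A called site is `inherited` when the
#' line additionally matches its parent line within the threshold
#' (`|beta_line - beta_parent| < theta`: epigenetic memory), and `aberrant`
#' when it differs from the parent by `>= theta` as well (a de novo
#' deviation); ties at exactly `theta` vs the parent count as aberrant,
#' consistent with inclusive DMR calling. Without a parent profile, or where
#' the parent is missing at a probe, the class is `unresolved`.
#'
#' @param line A [methylation_profile()] of one iPSC sample.
#' @param esc_avg ESC group-average [methylation_profile()].
#' @param parent Parent-line [methylation_profile()], or `NULL`.
#' @param theta Calling threshold; default 0.3.
#' @param line_name,passage Metadata recorded on the result.
#' @return An `es_ips_dmrs` tibble: `probe_id`, `beta_line`, `beta_esc`,
#'   `beta_parent`, `delta` (line - ESC), `direction`, `class`.
#' @export
call_es_ips_dmrs <- function(line, esc_avg, parent = NULL, theta = 0.3,
                             line_name = attr(line, "label"), passage = NA_integer_) {
  calls <- call_dmrs(line, esc_avg, theta)
  universe <- attr(calls, "universe")
  beta_parent <- rep(NA_real_, nrow(calls))
  if (!is.null(parent)) {
    beta_parent <- parent$beta[match(calls$probe_id, parent$probe_id)]
  }
  dp <- abs(calls$beta_a - beta_parent)
  class <- dplyr::case_when(
    is.na(beta_parent) ~ "unresolved",
    dp < theta ~ "inherited",
    TRUE ~ "aberrant"
  )
  structure(tibble(probe_id = calls$probe_id,
                   beta_line = calls$beta_a,
                   beta_esc = calls$beta_b,
                   beta_parent = beta_parent,
                   delta = calls$delta,
                   direction = calls$direction,
                   class = class),
            line = line_name,
            passage = as.integer(passage),
            theta = theta,
            universe = universe,
            class = c("es_ips_dmrs", class(tibble())))
}

#' @export
print.es_ips_dmrs <- function(x, ...) {
  cat(sprintf("# es_ips_dmrs: line '%s'%s, %d sites (%d inherited / %d aberrant / %d unresolved)\n",
              attr(x, "line") %||% "?",
              if (is.na(attr(x, "passage"))) "" else sprintf(" P%d", attr(x, "passage")),
              nrow(x), sum(x$class == "inherited"), sum(x$class == "aberrant"),
              sum(x$class == "unresolved")))
  NextMethod()
}

#' Cross-line overlap spectrum of ES-iPS-DMRs
#'
#' Tallies, for k = 1..L lines, how many probes are ES-iPS-DMRs in exactly k
#' of the L per-line call sets (each set one snapshot per line). The
#' conservation identity `sum(k * n_probes)` = total membership across lines
#' holds by construction.
#'
#' @param sets List of `es_ips_dmrs`, one per line.
#' @return Tibble `k`, `n_probes` (zero rows included up to L), with the
#'   per-probe membership counts as attribute `membership`.
#' @export
overlap_spectrum <- function(sets) {
  if (length(sets) < 2) abort("need >= 2 lines for an overlap spectrum")
  counts <- table(unlist(lapply(sets, function(s) unique(s$probe_id))) %||% character())
  L <- length(sets)
  tab <- tabulate(as.integer(counts), nbins = L)
  structure(tibble(k = seq_len(L), n_probes = as.integer(tab)),
            membership = tibble(probe_id = names(counts) %||% character(),
                                k = as.integer(counts)),
            class = c("overlap_spectrum", class(tibble())))
}

#' Probes recurrently aberrant across lines
#'
#' @param spectrum An [overlap_spectrum()] result.
#' @param k_min Minimum number of lines; default 15.
#' @return Character vector of probe ids that are ES-iPS-DMRs in `>= k_min`
#'   lines.
#' @export
probes_with_min_overlap <- function(spectrum, k_min = 15L) {
  mem <- attr(spectrum, "membership")
  if (is.null(mem)) abort("`spectrum` must come from overlap_spectrum()")
  sort(mem$probe_id[mem$k >= k_min])
}

#' Stratify ES-iPS-DMR calls by chromosome class, class, direction, island
#'
#' Produces the complete per-line contingency counts over
#' {autosome, X} x {inherited, aberrant, unresolved} x {hyper, hypo} x
#' {island, non-island}, with the line's sex attached. Y-chromosome sites are
#' counted under `chrom_class = "Y"` but are conventionally excluded from
#' X-chromosome comparisons.
#'
#' @param sets List of `es_ips_dmrs`, one per line.
#' @param ann Probe annotation tibble.
#' @param sheet Sample sheet tibble (source of per-line sex).
#' @return Tibble `line`, `sex`, `chrom_class`, `class`, `direction`,
#'   `cpg_island`, `n` (complete grid over autosome/X; marginals equal the
#'   per-line set sizes).
#' @export
stratify_dmrs <- function(sets, ann, sheet) {
  sheet <- validate_sample_sheet(sheet)
  sex_of <- sheet |>
    dplyr::distinct(.data$line_name, .data$sex)
  rows <- purrr::map_dfr(sets, function(s) {
    dplyr::mutate(as_tibble(s), line = attr(s, "line"))
  })
  rows <- rows |>
    dplyr::left_join(dplyr::select(ann, "probe_id", "chromosome", "cpg_island"),
                     by = "probe_id") |>
    dplyr::mutate(chrom_class = dplyr::case_when(
      .data$chromosome == "X" ~ "X",
      .data$chromosome == "Y" ~ "Y",
      TRUE ~ "autosome"
    )) |>
    dplyr::left_join(sex_of, by = c(line = "line_name"))
  if (any(is.na(rows$sex))) rows$sex[is.na(rows$sex)] <- "unknown"
  counts <- rows |>
    dplyr::count(.data$line, .data$sex, .data$chrom_class, .data$class,
                 .data$direction, .data$cpg_island, name = "n")
  # complete the autosome/X grid per line (Y rows kept as observed)
  grid_part <- counts |>
    dplyr::filter(.data$chrom_class != "Y") |>
    tidyr::complete(tidyr::nesting(line, sex),
                    chrom_class = c("autosome", "X"),
                    class = c("inherited", "aberrant", "unresolved"),
                    direction = c("hyper", "hypo"),
                    cpg_island = c(TRUE, FALSE),
                    fill = list(n = 0L))
  dplyr::arrange(dplyr::bind_rows(grid_part,
                                  dplyr::filter(counts, .data$chrom_class == "Y")),
                 .data$line, .data$chrom_class, .data$class,
                 .data$direction, .data$cpg_island)
}

#' Per-sex chrX summary of stratified counts
#'
#' @param strat Result of [stratify_dmrs()].
#' @return Tibble `sex`, `n_lines`, `mean_chrx_dmrs`, `mean_total_dmrs`.
#'   Lines of unknown sex are excluded with a warning.
#' @export
sex_summary <- function(strat) {
  unk <- unique(strat$line[strat$sex == "unknown"])
  if (length(unk)) {
    warn(paste("lines with unknown sex excluded from XX/XY summary:",
               paste(unk, collapse = ", ")))
  }
  strat |>
    dplyr::filter(.data$sex %in% c("XX", "XY")) |>
    dplyr::group_by(.data$sex, .data$line) |>
    dplyr::summarise(chrx = sum(.data$n[.data$chrom_class == "X"]),
                     total = sum(.data$n), .groups = "drop") |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(n_lines = dplyr::n(),
                     mean_chrx_dmrs = mean(.data$chrx),
                     mean_total_dmrs = mean(.data$total),
                     .groups = "drop")
}
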