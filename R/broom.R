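# broom-style tidiers for the package's composite result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy convergence_summary
#' @export
tidy.convergence_summary <- function(x, ...) as_tibble(as.data.frame(x))

#' Convergence flags of a cohort summary
#'
#' @param x A [convergence_summary()] or [parent_drift()] result.
#' @param ... Unused.
#' @return One-row tibble: `line`, first/last totals, the convergence flags.
#' @method glance convergence_summary
#' @export
glance.convergence_summary <- function(x, ...) {
  flags <- attr(x, "flags")
  tibble(line = attr(x, "line") %||% NA_character_,
         n_passages = nrow(x),
         total_first = x$total[1],
         total_last = x$total[nrow(x)],
         decreasing_total = flags$decreasing_total,
         de_novo_nonincreasing = flags$de_novo_nonincreasing,
         nondecreasing_total = flags$nondecreasing_total %||% NA)
}

#' @method tidy cohort_track
#' @export
tidy.cohort_track <- function(x, ...) tidy(convergence_summary(x))

#' @method glance cohort_track
#' @export
glance.cohort_track <- function(x, ...) glance(convergence_summary(x))

#' Per-probe ground-truth labels of a simulation
#'
#' @param x A `methyl_sim` from [simulate_methylation()].
#' @param ... Unused.
#' @return The label tibble of the ground truth.
#' @method tidy methyl_sim
#' @export
tidy.methyl_sim <- function(x, ...) x$truth$labels

#' @method glance methyl_sim
#' @export
glance.methyl_sim <- function(x, ...) {
  tibble(n_probes = x$config$n_probes,
         n_samples = nrow(x$sample_sheet),
         n_parent_sets = x$config$n_parent_sets,
         n_ipsc_lines = sum(x$config$lines_per_set),
         n_passages = length(x$config$passages),
         n_events = nrow(x$truth$events),
         seed = x$config$seed)
}

#' Stage counts of a pipeline run
#'
#' @param x A `methylpass_run` from [run_full_analysis()].
#' @param ... Unused.
#' @return Tibble `metric`, `value` of the manifest counts.
#' @method tidy methylpass_run
#' @export
tidy.methylpass_run <- function(x, ...) {
  cnt <- x$counts
  cnt$es_ips_dmrs_earliest <- NULL
  tibble(metric = names(cnt), value = as.integer(unlist(cnt)))
}

#' @method glance methylpass_run
#' @export
glance.methylpass_run <- function(x, ...) {
  tibble(n_probes_analyzed = x$counts$n_probes_analyzed,
         n_samples = x$counts$n_samples,
         n_ss_dmrs = x$counts$n_ss_dmrs,
         n_sc_required_dmrs = x$counts$n_sc_required_dmrs,
         config_hash = x$config_hash)
}
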