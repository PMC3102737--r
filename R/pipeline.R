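# Full-analysis orchestration: detection filter -> group averages -> per-set
# triads -> stem cell-specific / required DMRs -> per-line ES-iPS-DMRs ->
# passage cohorts -> reports, with a run manifest. Re-running on identical
# inputs reproduces byte-identical TSV/JSON outputs.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Read a flat JSON run configuration
#'
#' Keys: `beta`, `sample_sheet`, `annotation` (paths; required), `expression`
#' (path, optional), `out_dir`, and optional numeric overrides `theta`,
#' `alpha`, `high_cut`, `fold`, `k_min`, `theta_imprint`.
#'
#' @param path JSON file.
#' @return Named list of arguments for [run_full_analysis()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("run config not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("beta", "sample_sheet", "annotation", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) abort(paste("run config missing keys:", paste(miss, collapse = ", ")))
  cfg
}

#' Run the complete longitudinal DMR analysis
#'
#' Executes every stage of the analysis on a beta matrix with sample sheet
#' and probe annotation: detection-p filtering (when p-values are present),
#' the ESC group average with intra-group exclusion, the per-parent-set
#' seven-category partition, stem cell-specific and stem cell-required DMR
#' extraction with hyper/hypo and CpG-island composition (and expression
#' integration when an expression table is supplied), per-line ES-iPS-DMR
#' calling with inherited/aberrant decomposition at every passage, the
#' cross-line overlap spectrum and chromosome/sex stratification at each
#' line's earliest passage, passage cohort tracking with convergence
#' summaries and difference-value profiles for lines sampled at two or more
#' passages, parent-line drift, and an optional imprinted-locus screen.
#' Report files are written under `out_dir/tables` and `out_dir/json`;
#' the returned manifest records configuration, per-stage counts and a
#' config hash, and is written to `out_dir/manifest.json`.
#'
#' @param beta A [beta_matrix()] or path to one (`plain_tsv` dialect unless
#'   `dialect` says otherwise).
#' @param sample_sheet Sample-sheet tibble or CSV path.
#' @param annotation Annotation tibble or TSV path.
#' @param expression Optional expression tibble or TSV path.
#' @param out_dir Output directory (created).
#' @param theta DMR threshold; default 0.3.
#' @param alpha Detection p-value threshold; default 0.05.
#' @param high_cut High-methylation cut; default 0.6.
#' @param fold Expression fold-change threshold; default 5.
#' @param k_min Overlap threshold for the recurrent-DMR list; default 15.
#' @param imprint_loci Optional tibble of imprinted loci for
#'   [imprint_report()] (`probe_id`, optional `expected`, `locus`).
#' @param theta_imprint Imprint aberrance threshold; defaults to `theta`.
#' @param dialect Beta-matrix file dialect when `beta` is a path.
#' @return A `methylpass_run` manifest list, invisibly.
#' @export
run_full_analysis <- function(beta, sample_sheet, annotation, expression = NULL,
                              out_dir, theta = 0.3, alpha = 0.05,
                              high_cut = 0.6, fold = 5, k_min = 15L,
                              imprint_loci = NULL, theta_imprint = theta,
                              dialect = "plain_tsv") {
  config <- list(theta = theta, alpha = alpha, high_cut = high_cut,
                 fold = fold, k_min = as.integer(k_min),
                 theta_imprint = theta_imprint)

  x <- run_stage("load", {
    if (is.character(beta)) beta <- read_beta_matrix(beta, dialect = dialect)
    if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
    if (is.character(annotation)) annotation <- read_probe_annotation(annotation)
    if (is.character(expression)) {
      if (!file.exists(expression)) abort(sprintf("expression file not found: %s", expression))
      expression <- readr::read_tsv(expression, show_col_types = FALSE, progress = FALSE)
    }
    beta
  })
  sheet <- validate_sample_sheet(sample_sheet)
  ann <- validate_probe_annotation(annotation)

  n_input <- nrow(x)
  x <- run_stage("detection_filter", {
    if (!is.null(detection_p(x))) filter_by_detection(x, alpha) else x
  })
  run_stage("validate", validate_dataset(x, sheet, ann))

  dir.create(file.path(out_dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "json"), recursive = TRUE, showWarnings = FALSE)
  tbl_path <- function(...) file.path(out_dir, "tables", ...)
  json_path <- function(...) file.path(out_dir, "json", ...)
  wjson <- function(obj, path) {
    jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }

  esc <- run_stage("esc_average", esc_average(x, sheet, theta = theta))

  categories <- run_stage("category_partition",
                          categorize_parent_sets(x, sheet, theta = theta))
  ss <- run_stage("stem_cell_specific", stem_cell_specific_dmrs(categories))
  required <- run_stage("stem_cell_required", stem_cell_required_dmrs(categories))
  comp <- run_stage("composition", composition_report(ss, ann))
  run_stage("category_outputs", {
    readr::write_tsv(dplyr::left_join(ss, dplyr::select(ann, "probe_id", "gene_symbol"),
                                      by = "probe_id"),
                     tbl_path("ss_dmrs.tsv"), progress = FALSE)
    readr::write_tsv(dplyr::left_join(required, dplyr::select(ann, "probe_id", "gene_symbol"),
                                      by = "probe_id"),
                     tbl_path("sc_required_dmrs.tsv"), progress = FALSE)
    wjson(comp, json_path("composition.json"))
  })

  expr_classes <- NULL
  if (!is.null(expression)) {
    expr_classes <- run_stage("expression_integration",
                              integrate_expression(ss, expression, sheet, ann, fold = fold))
    readr::write_tsv(expr_classes, tbl_path("expression_integration.tsv"), progress = FALSE)
  }

  # per-line ES-iPS-DMR calls at every analysed passage
  ipsc <- sheet[sheet$role == "iPSC", ]
  lines <- sort(unique(ipsc$line_name))
  parent_of <- function(ps) {
    smp <- earliest_passage_samples(sheet, role = "parent", parent_set = ps)
    sample_profile(x, smp[1], label = paste0(ps, "-parent"))
  }
  parent_profiles <- run_stage("parent_profiles", {
    sets <- sort(unique(ipsc$parent_set))
    stats::setNames(lapply(sets, parent_of), sets)
  })

  line_series <- run_stage("es_ips_calls", {
    stats::setNames(lapply(lines, function(ln) {
      rows <- dplyr::arrange(ipsc[ipsc$line_name == ln, ], .data$passage)
      lapply(seq_len(nrow(rows)), function(i) {
        call_es_ips_dmrs(sample_profile(x, rows$sample_id[i], label = ln),
                         esc, parent_profiles[[rows$parent_set[i]]],
                         theta = theta, line_name = ln, passage = rows$passage[i])
      })
    }), lines)
  })
  earliest_sets <- lapply(line_series, function(sr) sr[[1]])
  run_stage("es_ips_outputs", {
    for (ln in lines) {
      s <- earliest_sets[[ln]]
      readr::write_tsv(dplyr::arrange(as_tibble(s), .data$probe_id),
                       tbl_path(sprintf("es_ips_dmrs_%s_P%d.tsv", ln, attr(s, "passage"))),
                       progress = FALSE)
    }
  })

  spectrum <- run_stage("overlap_spectrum", {
    if (length(earliest_sets) >= 2) overlap_spectrum(unname(earliest_sets)) else NULL
  })
  recurrent <- NULL
  if (!is.null(spectrum)) {
    recurrent <- probes_with_min_overlap(spectrum, k_min)
    readr::write_tsv(as_tibble(spectrum), tbl_path("overlap_spectrum.tsv"), progress = FALSE)
  }

  strat <- run_stage("stratification", stratify_dmrs(unname(earliest_sets), ann, sheet))
  sexsum <- suppressWarnings(sex_summary(strat))
  wjson(list(by_line = strat, by_sex = sexsum), json_path("stratification.json"))

  # longitudinal: lines with >= 2 passages
  convergence <- list()
  run_stage("longitudinal", {
    for (ln in lines) {
      sr <- line_series[[ln]]
      if (length(sr) < 2) next
      track <- build_cohorts(sr)
      summ <- convergence_summary(track)
      rows <- dplyr::arrange(ipsc[ipsc$line_name == ln, ], .data$passage)
      series <- stats::setNames(lapply(rows$sample_id, function(s) sample_profile(x, s)),
                                rows$passage)
      first_cohort <- unique(track$probe_id[track$first_passage == attr(track, "passages")[1]])
      dp <- difference_profile(series, esc, first_cohort)
      readr::write_tsv(as_tibble(track), tbl_path(sprintf("cohorts_%s.tsv", ln)),
                       progress = FALSE)
      convergence[[ln]] <- list(summary = as_tibble(summ),
                                 flags = attr(summ, "flags"),
                                 difference = difference_summary(dp))
    }
  })

  parent_conv <- list()
  run_stage("parent_drift", {
    parents <- sheet[sheet$role == "parent", ]
    for (ln in sort(unique(parents$line_name))) {
      rows <- dplyr::arrange(parents[parents$line_name == ln, ], .data$passage)
      if (nrow(rows) < 2) next
      series <- stats::setNames(lapply(rows$sample_id, function(s) sample_profile(x, s)),
                                rows$passage)
      summ <- parent_drift(series, esc, theta = theta, line_name = ln)
      parent_conv[[ln]] <- list(summary = as_tibble(summ), flags = attr(summ, "flags"))
    }
  })
  wjson(list(ipsc = convergence, parent = parent_conv), json_path("convergence.json"))

  imprint <- NULL
  if (!is.null(imprint_loci)) {
    imprint <- run_stage("imprint_report", {
      all_lines <- sheet |>
        dplyr::distinct(.data$line_name)
      profs <- stats::setNames(lapply(all_lines$line_name, function(ln) {
        smp <- sheet[sheet$line_name == ln, ]
        smp <- dplyr::arrange(smp, is.na(.data$passage), .data$passage)
        sample_profile(x, smp$sample_id[1], label = ln)
      }), all_lines$line_name)
      imprint_report(profs, imprint_loci, theta_imprint = theta_imprint)
    })
    readr::write_tsv(imprint, tbl_path("imprint_report.tsv"), progress = FALSE)
  }

  manifest <- list(
    package = "methylpass",
    version = as.character(utils::packageVersion("methylpass")),
    config = config,
    config_hash = rlang::hash(config),
    counts = list(
      n_samples = ncol(x) - 1L,
      n_probes_input = n_input,
      n_probes_analyzed = nrow(x),
      n_parent_sets = length(parent_profiles),
      n_ipsc_lines = length(lines),
      n_ss_dmrs = nrow(ss),
      n_sc_required_dmrs = nrow(required),
      es_ips_dmrs_earliest = stats::setNames(
        vapply(earliest_sets, nrow, integer(1)), lines),
      n_recurrent_dmrs = if (is.null(recurrent)) NA_integer_ else length(recurrent)
    )
  )
  wjson(manifest, file.path(out_dir, "manifest.json"))

  invisible(structure(c(manifest,
                        list(ss = ss, required = required, composition = comp,
                             expression_classes = expr_classes,
                             spectrum = spectrum, stratification = strat,
                             sex_summary = sexsum, convergence = convergence,
                             parent_convergence = parent_conv,
                             imprint = imprint, out_dir = out_dir)),
                      class = "methylpass_run"))
}

#' @export
print.methylpass_run <- function(x, ...) {
  cat(sprintf(paste0("# methylpass run: %d probes / %d samples analysed\n",
                     "#   stem cell-specific DMRs: %d; stem cell-required: %d\n",
                     "#   outputs under: %s\n"),
              x$counts$n_probes_analyzed, x$counts$n_samples,
              x$counts$n_ss_dmrs, x$counts$n_sc_required_dmrs, x$out_dir))
  invisible(x)
}
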