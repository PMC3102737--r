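# Seven-category overlap partition of probes for one parent-cell set
# (ESC vs parent, iPSC vs parent, ESC vs iPSC call sets), and the stem
# cell-specific / stem cell-required DMR extraction built on it.
#
# Letter mapping (fixed convention; only ee/bb/ff matter analytically):
#   aa  ESC-vs-parent only
#   bb  iPSC-vs-parent and ESC-vs-iPSC (iPSC-specific DMRs)
#   cc  iPSC-vs-parent only
#   dd  ESC-vs-iPSC only
#   ee  ESC-vs-parent and iPSC-vs-parent, not ESC-vs-iPSC
#       (stem cells jointly differ from the parent: the SS-DMR pattern)
#   ff  ESC-vs-parent and ESC-vs-iPSC, not iPSC-vs-parent
#       (iPSC matches parent: inherited pattern)
#   gg  all three

CATEGORY_LEVELS <- c("none", "aa", "bb", "cc", "dd", "ee", "ff", "gg")

category_from_membership <- function(in_ep, in_ip, in_ei) {
  key <- in_ep * 4L + in_ip * 2L + in_ei
  # key: EP,IP,EI bits
  map <- c("none", # 000
           "dd",   # 001 EI only
           "cc",   # 010 IP only
           "bb",   # 011 IP & EI
           "aa",   # 100 EP only
           "ff",   # 101 EP & EI
           "ee",   # 110 EP & IP
           "gg")   # 111
  map[key + 1L]
}

#' Partition probes into the seven overlap categories
#'
#' Given the three DMR call sets of one parent-cell set -- ESC vs parent
#' (`d_ep`), iPSC vs parent (`d_ip`) and ESC vs iPSC (`d_ei`), all computed
#' at the same threshold on one shared probe universe -- assigns each probe
#' of the universe the unique category matching its membership pattern
#' (see the mapping in the source header). Probes in no call set are
#' `"none"`.
#'
#' @param d_ep,d_ip,d_ei `dmr_calls` from [call_dmrs()] on one universe.
#' @param parent_set Label of the parent-cell set.
#' @return A `category_table` tibble: `probe_id`, `category`, membership
#'   flags `in_ep`/`in_ip`/`in_ei`, and `direction_ip` (iPSC-vs-parent
#'   direction, NA where the probe is not in `d_ip`).
#' @export
partition_categories <- function(d_ep, d_ip, d_ei, parent_set = "set") {
  sets <- list(d_ep, d_ip, d_ei)
  if (!all(vapply(sets, inherits, logical(1), "dmr_calls"))) {
    abort("`d_ep`, `d_ip`, `d_ei` must be dmr_calls objects")
  }
  universes <- lapply(sets, attr, "universe")
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]]))) {
    abort("the three call sets do not share one probe universe")
  }
  thetas <- vapply(sets, attr, numeric(1), "theta")
  if (length(unique(thetas)) != 1) abort("the three call sets use different thresholds")
  universe <- universes[[1]]
  in_ep <- universe %in% d_ep$probe_id
  in_ip <- universe %in% d_ip$probe_id
  in_ei <- universe %in% d_ei$probe_id
  structure(tibble(probe_id = universe,
                   category = category_from_membership(in_ep, in_ip, in_ei),
                   in_ep = in_ep, in_ip = in_ip, in_ei = in_ei,
                   direction_ip = d_ip$direction[match(universe, d_ip$probe_id)]),
            parent_set = parent_set,
            theta = thetas[1],
            class = c("category_table", class(tibble())))
}

#' Build per-parent-set category tables from a full dataset
#'
#' For each parent-cell set, forms the triad of group comparisons -- the ESC
#' group average (intra-group exclusion applied) vs the set's parent line,
#' the set's iPSC group average vs the parent, and ESC vs iPSC -- and
#' partitions the shared probe universe into the seven categories. iPSC
#' groups use one sample per line: its earliest analysed passage. The parent
#' profile is the parent line's earliest analysed passage.
#'
#' @param x A [beta_matrix()].
#' @param sheet Sample sheet tibble covering all samples of `x`.
#' @param theta DMR threshold; default 0.3.
#' @param intra_exclude Apply intra-group DMR exclusion to group averages?
#' @return Tibble of stacked category tables: `parent_set`, `probe_id`,
#'   `category`, membership flags, `direction_ip`.
#' @export
categorize_parent_sets <- function(x, sheet, theta = 0.3, intra_exclude = TRUE) {
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(sample_ids(x), sheet$sample_id)
  if (length(miss)) {
    abort(paste("samples missing from sample sheet:", paste(miss, collapse = ", ")))
  }
  esc <- esc_average(x, sheet, theta = theta, intra_exclude = intra_exclude)
  sets <- sort(unique(sheet$parent_set[sheet$role == "iPSC" & !is.na(sheet$parent_set)]))
  if (length(sets) < 1) abort("no iPSC parent sets in sample sheet")
  purrr::map_dfr(sets, function(ps) {
    ip_members <- earliest_passage_samples(sheet, role = "iPSC", parent_set = ps)
    parent_smp <- earliest_passage_samples(sheet, role = "parent", parent_set = ps)
    ip_avg <- group_average(x, ip_members, intra_exclude = intra_exclude,
                            theta = theta, label = paste0(ps, "-iPSC"))
    par_prof <- if (length(parent_smp) > 1) {
      group_average(x, parent_smp, intra_exclude = intra_exclude,
                    theta = theta, label = paste0(ps, "-parent"))
    } else {
      sample_profile(x, parent_smp, label = paste0(ps, "-parent"))
    }
    tab <- partition_categories(call_dmrs(esc, par_prof, theta),
                                call_dmrs(ip_avg, par_prof, theta),
                                call_dmrs(esc, ip_avg, theta),
                                parent_set = ps)
    dplyr::mutate(as_tibble(tab), parent_set = ps, .before = 1)
  })
}

# ESC reference profile: intra-exclusion group average over all ESC samples
esc_average <- function(x, sheet, theta = 0.3, intra_exclude = TRUE) {
  esc_samples <- sheet$sample_id[sheet$role == "ESC"]
  if (!length(esc_samples)) abort("no ESC samples in sample sheet")
  group_average(x, esc_samples, intra_exclude = intra_exclude,
                theta = theta, label = "ESC")
}

# one sample per line: earliest analysed passage (NA passages sort last)
earliest_passage_samples <- function(sheet, role, parent_set = NULL) {
  rows <- sheet[sheet$role == role, ]
  if (!is.null(parent_set)) rows <- rows[!is.na(rows$parent_set) & rows$parent_set == parent_set, ]
  if (!nrow(rows)) abort(sprintf("no %s samples for parent set '%s'", role, parent_set %||% "?"))
  picked <- rows |>
    dplyr::group_by(.data$line_name) |>
    dplyr::arrange(is.na(.data$passage), .data$passage, .data$sample_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  picked$sample_id
}

#' Stem cell-specific DMRs
#'
#' Probes whose category is `"ee"` (ESC and iPSC jointly differ from the
#' parent, while ESC and iPSC agree) in every parent-cell set -- the
#' reprogramming-invariant methylation signature of the stem-cell state.
#' Direction is taken from the iPSC-vs-parent comparison (hyper = more
#' methylated in stem cells than in parents) and checked for consistency
#' across sets.
#'
#' @param cat_tables Stacked category tables from [categorize_parent_sets()].
#' @return Tibble `probe_id`, `direction`, `n_sets` (= number of parent
#'   sets, by construction).
#' @export
stem_cell_specific_dmrs <- function(cat_tables) {
  n_total <- dplyr::n_distinct(cat_tables$parent_set)
  if (n_total < 2) abort("need >= 2 parent sets")
  ee <- dplyr::filter(cat_tables, .data$category == "ee")
  out <- ee |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(n_sets = dplyr::n(),
                     n_dir = dplyr::n_distinct(.data$direction_ip),
                     direction = .data$direction_ip[1],
                     .groups = "drop") |>
    dplyr::filter(.data$n_sets == n_total)
  if (any(out$n_dir > 1)) {
    warn(sprintf("%d stem cell-specific DMR(s) with inconsistent direction across sets",
                 sum(out$n_dir > 1)))
  }
  dplyr::arrange(dplyr::select(out, "probe_id", "direction", "n_sets"), .data$probe_id)
}

#' Stem cell-required DMRs
#'
#' Probes with the `"ee"` pattern in one or more parent-cell sets -- the
#' union counterpart of [stem_cell_specific_dmrs()], retaining which sets
#' contributed each probe.
#'
#' @inheritParams stem_cell_specific_dmrs
#' @return Tibble `probe_id`, `direction`, `n_sets`, `parent_sets`
#'   (comma-separated contributing sets).
#' @export
stem_cell_required_dmrs <- function(cat_tables) {
  ee <- dplyr::filter(cat_tables, .data$category == "ee")
  ee |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(direction = .data$direction_ip[1],
                     n_sets = dplyr::n(),
                     parent_sets = paste(sort(.data$parent_set), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$probe_id)
}

#' Hyper/hypo and CpG-island composition of a probe set
#'
#' @param probes Tibble with `probe_id` and `direction` columns (e.g. from
#'   [stem_cell_specific_dmrs()]).
#' @param ann Probe annotation tibble.
#' @return Tibble with one row per direction: `direction`, `n`, `fraction`
#'   (of the whole set), `n_island`, `island_fraction` (within direction).
#'   Fractions sum to 1 within each breakdown.
#' @export
composition_report <- function(probes, ann) {
  joined <- dplyr::left_join(probes, ann, by = "probe_id")
  if (any(is.na(joined$cpg_island))) {
    abort("some probes lack annotation; run validate_dataset() first")
  }
  total <- nrow(joined)
  joined |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(n = dplyr::n(),
                     n_island = sum(.data$cpg_island),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n / total,
                  island_fraction = .data$n_island / .data$n) |>
    dplyr::select("direction", "n", "fraction", "n_island", "island_fraction") |>
    dplyr::arrange(.data$direction)
}

#' Cross methylation direction with expression fold change
#'
#' Classifies the genes behind a probe set by their expression ratio between
#' stem-cell samples (ESC and iPSC) and parent samples: `"high"` when the
#' stem/parent mean ratio exceeds `fold`, `"low"` when the parent/stem ratio
#' does, otherwise `"unclassified"`; genes absent from the expression matrix
#' are `"unmeasured"`. Intensities are linear; a group mean of zero is
#' replaced by `pseudocount` before forming ratios. When several probes
#' annotate one gene the probe with the largest `|delta|` represents it
#' (requires a `delta` column; otherwise the first probe is used).
#'
#' @param probes Tibble with `probe_id`, `direction` and optionally `delta`.
#' @param expr Expression tibble: `gene` column plus one numeric column per
#'   sample (linear intensities).
#' @param sheet Sample sheet tibble (defines stem vs parent groups).
#' @param ann Probe annotation tibble (maps probes to gene symbols).
#' @param fold Fold-change threshold (> 1); default 5.
#' @param pseudocount Replacement for zero group means; default 1.
#' @return Tibble `gene`, `probe_id`, `direction`, `stem_mean`,
#'   `parent_mean`, `ratio` (stem/parent), `expression_class`.
#' @export
integrate_expression <- function(probes, expr, sheet, ann, fold = 5, pseudocount = 1) {
  if (!is.numeric(fold) || fold <= 1) abort("`fold` must be > 1")
  sheet <- validate_sample_sheet(sheet)
  stem_smp <- intersect(sheet$sample_id[sheet$role %in% c("ESC", "iPSC")], names(expr))
  parent_smp <- intersect(sheet$sample_id[sheet$role == "parent"], names(expr))
  if (!length(stem_smp) || !length(parent_smp)) {
    abort("expression matrix lacks stem-cell or parent samples")
  }
  mapped <- probes |>
    dplyr::left_join(dplyr::select(ann, "probe_id", gene = "gene_symbol"), by = "probe_id")
  if (!"delta" %in% names(mapped)) mapped$delta <- NA_real_
  mapped <- mapped |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta)), .data$probe_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  em <- as.matrix(expr[, c(stem_smp, parent_smp), drop = FALSE])
  rownames(em) <- expr$gene
  idx <- match(mapped$gene, rownames(em))
  stem_mean <- unname(rowMeans(em[, stem_smp, drop = FALSE])[idx])
  parent_mean <- unname(rowMeans(em[, parent_smp, drop = FALSE])[idx])
  sm <- ifelse(!is.na(stem_mean) & stem_mean == 0, pseudocount, stem_mean)
  pm <- ifelse(!is.na(parent_mean) & parent_mean == 0, pseudocount, parent_mean)
  ratio <- sm / pm
  class <- dplyr::case_when(
    is.na(idx) ~ "unmeasured",
    ratio > fold ~ "high",
    1 / ratio > fold ~ "low",
    TRUE ~ "unclassified"
  )
  tibble(gene = mapped$gene,
         probe_id = mapped$probe_id,
         direction = mapped$direction,
         stem_mean = stem_mean,
         parent_mean = parent_mean,
         ratio = ratio,
         expression_class = class) |>
    dplyr::arrange(.data$gene)
}
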