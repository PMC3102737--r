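# Reading, writing and validation of beta-value matrices, sample sheets and
# probe annotations. The pipeline starts at beta values: no IDAT parsing,
# normalisation or batch correction happens here.

BETA_DIALECTS <- c("plain_tsv", "illumina_report")
ROLE_LEVELS <- c("ESC", "iPSC", "parent")
SEX_LEVELS <- c("XX", "XY", "unknown")
CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

#' Construct a beta-value matrix object
#'
#' A `beta_matrix` is a tibble with a `probe_id` character column followed by
#' one numeric column per sample, holding Infinium-style methylation scores
#' (beta values) in \[0, 1\]: 0 = completely unmethylated, 1 = completely
#' methylated. Missing (masked) entries are `NA` and are excluded from every
#' downstream mean and comparison. An optional per-entry detection p-value
#' matrix is carried as an attribute.
#'
#' @param x Tibble or data frame: `probe_id` plus one numeric column per
#'   sample. Probe and sample identifiers must be unique; non-missing values
#'   must lie in \[0, 1\] (out-of-range values are an error, never clamped).
#' @param detection_p Optional numeric matrix of detection p-values with the
#'   same probe x sample shape (rownames = probe ids, colnames = sample ids).
#' @return A `beta_matrix` tibble.
#' @export
beta_matrix <- function(x, detection_p = NULL) {
  x <- as_tibble(x)
  if (ncol(x) < 2 || names(x)[1] != "probe_id") {
    abort("a beta matrix needs a leading `probe_id` column plus >= 1 sample column")
  }
  x$probe_id <- as.character(x$probe_id)
  if (anyDuplicated(x$probe_id)) {
    abort(paste0("duplicate probe ids: ",
                 paste(unique(x$probe_id[duplicated(x$probe_id)]), collapse = ", ")))
  }
  smp <- names(x)[-1]
  if (anyDuplicated(smp)) abort("duplicate sample ids in beta matrix")
  for (s in smp) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(sprintf("sample '%s': beta values must be numeric", s))
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      abort(sprintf("beta value out of [0, 1] at probe '%s', sample '%s' (value %g)",
                    x$probe_id[bad[1]], s, v[bad[1]]))
    }
  }
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), c(nrow(x), length(smp)))) {
      abort("`detection_p` must share the beta matrix dimensions")
    }
    bad <- which(!is.na(detection_p) & (detection_p < 0 | detection_p > 1))
    if (length(bad)) abort("detection p-values must lie in [0, 1]")
    dimnames(detection_p) <- list(x$probe_id, smp)
  }
  structure(x,
            detection_p = detection_p,
            class = c("beta_matrix", class(as_tibble(x))))
}

#' @export
print.beta_matrix <- function(x, ...) {
  dp <- attr(x, "detection_p")
  cat(sprintf("# beta_matrix: %d probes x %d samples%s\n",
              nrow(x), ncol(x) - 1L,
              if (is.null(dp)) "" else " (with detection p-values)"))
  NextMethod()
}

#' Extract the numeric beta matrix (probes x samples)
#'
#' @param x A `beta_matrix`.
#' @return Numeric matrix with probe ids as rownames.
#' @export
beta_values <- function(x) {
  stopifnot(inherits(x, "beta_matrix"))
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$probe_id
  m
}

#' @rdname beta_values
#' @export
detection_p <- function(x) attr(x, "detection_p")

#' Sample identifiers of a beta matrix
#' @param x A `beta_matrix`.
#' @export
sample_ids <- function(x) names(x)[-1]

#' Read a beta-value matrix
#'
#' Two dialects are supported. `plain_tsv`: first column `probe_id`, one
#' tab-separated column per sample, `"NA"` for missing. `illumina_report`:
#' a `TargetID` column plus, per sample, `<name>.AVG_Beta` and (optionally)
#' `<name>.Detection Pval` columns, as emitted by BeadStudio-style final
#' reports. Values outside \[0, 1\], non-numeric cells and duplicated probe
#' ids are rejected with the offending probe/sample named.
#'
#' @param path File to read.
#' @param dialect `"plain_tsv"` (default) or `"illumina_report"`.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, dialect = c("plain_tsv", "illumina_report")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("beta matrix file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (dialect == "plain_tsv") {
    names(raw)[1] <- "probe_id"
    parse_beta_columns(raw, probe_col = "probe_id")
  } else {
    if (!"TargetID" %in% names(raw)) {
      abort("illumina_report dialect requires a 'TargetID' column")
    }
    beta_cols <- grep("\\.AVG_Beta$", names(raw), value = TRUE)
    if (!length(beta_cols)) abort("illumina_report dialect: no '<sample>.AVG_Beta' columns found")
    samples <- sub("\\.AVG_Beta$", "", beta_cols)
    tb <- raw[, c("TargetID", beta_cols)]
    names(tb) <- c("probe_id", samples)
    out <- parse_beta_columns(tb, probe_col = "probe_id")
    pval_cols <- paste0(samples, ".Detection Pval")
    if (any(pval_cols %in% names(raw))) {
      dp <- matrix(NA_real_, nrow(raw), length(samples),
                   dimnames = list(out$probe_id, samples))
      for (i in seq_along(samples)) {
        pc <- pval_cols[i]
        if (pc %in% names(raw)) {
          dp[, i] <- parse_numeric_cells(raw[[pc]], out$probe_id, samples[i], "detection p-value")
        }
      }
      out <- beta_matrix(out, detection_p = dp)
    }
    out
  }
}

parse_numeric_cells <- function(chr, probes, sample, what) {
  chr[chr %in% c("NA", "")] <- NA
  v <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(v) & !is.na(chr))
  if (length(bad)) {
    abort(sprintf("non-numeric %s '%s' at probe '%s', sample '%s'",
                  what, chr[bad[1]], probes[bad[1]], sample))
  }
  v
}

parse_beta_columns <- function(tb, probe_col) {
  probes <- tb[[probe_col]]
  out <- tibble(probe_id = probes)
  for (s in setdiff(names(tb), probe_col)) {
    out[[s]] <- parse_numeric_cells(tb[[s]], probes, s, "beta value")
  }
  beta_matrix(out)
}

#' Write a beta-value matrix
#'
#' `plain_tsv` writes the probe/sample table as tab-separated text with `NA`
#' for missing entries; a write/read round trip is value-exact and, for files
#' produced by this writer, byte-identical. `illumina_report` writes
#' `TargetID`, `<sample>.AVG_Beta` and (when present) `<sample>.Detection
#' Pval` columns.
#'
#' @param x A [beta_matrix()].
#' @param path Output file.
#' @param dialect Output dialect, as in [read_beta_matrix()].
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, dialect = c("plain_tsv", "illumina_report")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "beta_matrix"))
  if (dialect == "plain_tsv") {
    readr::write_tsv(as_tibble(as.data.frame(x)), path, na = "NA", progress = FALSE)
  } else {
    dp <- detection_p(x)
    out <- tibble(TargetID = x$probe_id)
    for (s in sample_ids(x)) {
      out[[paste0(s, ".AVG_Beta")]] <- x[[s]]
      if (!is.null(dp)) out[[paste0(s, ".Detection Pval")]] <- dp[, s]
    }
    readr::write_tsv(out, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Drop probes failing the detection p-value filter
#'
#' A probe is eliminated from the shared probe universe (row-wise, across all
#' samples) when its detection p-value is `>= alpha` in any sample: the
#' boundary is inclusive, so a probe at exactly `alpha` fails. The operation
#' is idempotent. Missing p-values count as passing.
#'
#' @param x A [beta_matrix()] with detection p-values.
#' @param alpha Detection p-value threshold in (0, 1\]; default 0.05.
#' @return A filtered [beta_matrix()].
#' @export
filter_by_detection <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "beta_matrix"))
  assert_scalar_prob(alpha, "alpha", lo_open = TRUE)
  dp <- detection_p(x)
  if (is.null(dp)) {
    abort(paste("no detection p-values present; read the matrix with the",
                "illumina_report dialect or pass the data through unfiltered"))
  }
  fails <- rowSums(dp >= alpha, na.rm = TRUE) > 0
  beta_matrix(as_tibble(as.data.frame(x))[!fails, , drop = FALSE],
              detection_p = dp[!fails, , drop = FALSE])
}

#' Read a sample sheet
#'
#' CSV with header `sample_id,line_name,role,parent_set,sex,passage`. Roles
#' are restricted to ESC / iPSC / parent; sex to XX / XY / unknown; passage is
#' a non-negative integer or empty.
#'
#' @param path CSV file.
#' @return Tibble with those six columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("sample sheet not found: %s", path))
  sheet <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    line_name = readr::col_character(),
    role = readr::col_character(),
    parent_set = readr::col_character(),
    sex = readr::col_character(),
    passage = readr::col_integer()
  ), progress = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet tibble to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "line_name", "role", "parent_set", "sex", "passage")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) abort(paste("sample sheet missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(sheet$role), ROLE_LEVELS)
  if (length(bad)) abort(paste("invalid role(s):", paste(bad, collapse = ", ")))
  sheet$sex[is.na(sheet$sex)] <- "unknown"
  bad <- setdiff(unique(sheet$sex), SEX_LEVELS)
  if (length(bad)) abort(paste("invalid sex value(s):", paste(bad, collapse = ", ")))
  if (any(!is.na(sheet$passage) & sheet$passage < 0)) abort("passage numbers must be >= 0")
  ipsc_sets <- unique(sheet$parent_set[sheet$role == "iPSC"])
  parent_sets <- unique(sheet$parent_set[sheet$role == "parent"])
  orphan <- setdiff(ipsc_sets[!is.na(ipsc_sets)], parent_sets)
  if (length(orphan)) {
    abort(paste("iPSC parent_set(s) without a matching parent line:",
                paste(orphan, collapse = ", ")))
  }
  as_tibble(sheet)
}

#' Write a sample sheet
#' @param sheet Sample-sheet tibble.
#' @param path Output CSV file.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' TSV with header `probe_id,gene_symbol,chromosome,cpg_island`
#' (`cpg_island` coded 0/1). Chromosomes must be 1-22, X or Y.
#'
#' @param path TSV file.
#' @return Tibble with `cpg_island` as logical.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("probe annotation not found: %s", path))
  ann <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    chromosome = readr::col_character(),
    cpg_island = readr::col_integer()
  ), progress = FALSE)
  validate_probe_annotation(dplyr::mutate(ann, cpg_island = .data$cpg_island == 1L))
}

#' @rdname read_probe_annotation
#' @param ann An annotation tibble to validate in place.
#' @export
validate_probe_annotation <- function(ann) {
  need <- c("probe_id", "gene_symbol", "chromosome", "cpg_island")
  miss <- setdiff(need, names(ann))
  if (length(miss)) abort(paste("annotation missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(ann$probe_id)) abort("duplicate probe ids in annotation")
  bad <- setdiff(unique(as.character(ann$chromosome)), CHROM_LEVELS)
  if (length(bad)) abort(paste("invalid chromosome(s):", paste(bad, collapse = ", ")))
  dplyr::mutate(as_tibble(ann),
                chromosome = as.character(.data$chromosome),
                cpg_island = as.logical(.data$cpg_island))
}

#' Write a probe annotation table
#' @param ann Annotation tibble (`cpg_island` logical or 0/1).
#' @param path Output TSV file.
#' @export
write_probe_annotation <- function(ann, path) {
  out <- dplyr::mutate(ann, cpg_island = as.integer(.data$cpg_island))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Check that beta matrix, sample sheet and annotation agree
#'
#' The sample-sheet join must be total (every beta-matrix sample has
#' metadata) and every probe must have exactly one annotation row; the
#' pipeline refuses to start otherwise.
#'
#' @param x A [beta_matrix()].
#' @param sheet Sample sheet tibble.
#' @param ann Probe annotation tibble.
#' @return `TRUE`, invisibly; errors describe the first inconsistency.
#' @export
validate_dataset <- function(x, sheet, ann) {
  sheet <- validate_sample_sheet(sheet)
  ann <- validate_probe_annotation(ann)
  miss <- setdiff(sample_ids(x), sheet$sample_id)
  if (length(miss)) {
    abort(paste("samples missing from sample sheet:", paste(miss, collapse = ", ")))
  }
  miss <- setdiff(x$probe_id, ann$probe_id)
  if (length(miss)) {
    abort(sprintf("%d probe(s) missing from annotation (first: %s)",
                  length(miss), miss[1]))
  }
  invisible(TRUE)
}
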