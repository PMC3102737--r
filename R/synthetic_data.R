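# Stochastic generator of beta-value datasets with the structure the
# analysis assumes: stem-cell-specific hypo/hyper sites shared by ESCs and
# iPSCs, parent-line-specific sites with a memory-prone subset that iPSC
# lines inherit, per-passage de novo hyper-methylation whose rate decays
# geometrically, reversion (selection) toward the ESC level, elevated and
# transient chrX event rates in XX lines, drifting parent lines, and fixed
# imprint aberrations. Every stochastic event is logged so that emitted
# matrices can be reconstructed exactly from the ground truth.

DEFAULT_SET_NAMES <- c("MRC", "AM", "UtE", "PAE", "Edom")
DEFAULT_SET_SEX <- c(MRC = "XY", AM = "XX", UtE = "XX", PAE = "XY", Edom = "XX")

#' Simulation configuration
#'
#' Returns a validated configuration for [simulate_methylation()]. The
#' defaults describe the study design the analysis targets: ~25,000 probes,
#' five ESC lines, five parent-cell sets contributing 22 iPSC lines sampled
#' at four passages, the 0.3 calling threshold, 220 planted stem
#' cell-specific sites (174 hyper + 46 hypo in stem cells), and event rates
#' chosen so that de novo appearance counts fall from roughly 130 at the
#' first sampled passage to below 20 at the last while parent lines drift
#' away from the ESC profile without converging.
#'
#' @param n_probes Number of CpG probes.
#' @param n_parent_sets Number of parent-cell sets.
#' @param lines_per_set iPSC lines per set (recycled).
#' @param esc_lines Number of ESC lines.
#' @param passages Sampled iPSC passages, strictly increasing.
#' @param parent_passages Sampled parent passages, strictly increasing.
#' @param frac_island Baseline CpG-island fraction of probes.
#' @param island_frac_ss_hypo,island_frac_ss_hyper Island probability for
#'   planted stem-cell hypo/hyper sites (hypo sites are island-biased, hyper
#'   sites non-island-biased).
#' @param frac_chrX Fraction of probes on the X chromosome.
#' @param frac_methylated Fraction of background probes methylated in the
#'   ESC reference.
#' @param mu0,mu1 Unmethylated / methylated beta levels.
#' @param noise_sd SD of the per-entry truncated Gaussian noise.
#' @param theta DMR threshold carried into analysis defaults.
#' @param high_cut High-methylation cut carried into analysis defaults.
#' @param n_ss_hyper,n_ss_hypo Planted stem cell-specific sites that are
#'   hyper/hypo-methylated in stem cells relative to parents.
#' @param n_parent_specific Parent-line-specific differential sites per set.
#' @param memory_pool Size of the memory-prone subset of each set's
#'   parent-specific sites from which inherited sites are drawn.
#' @param n_inherited Inherited (memory) sites per iPSC line.
#' @param frac_parent_hyper Fraction of parent-specific sites methylated in
#'   the parent (and unmethylated in ESCs).
#' @param r_denovo De novo hyper-methylation probability per eligible probe
#'   at the first sampled passage.
#' @param gamma Geometric decay of the de novo rate per sampled passage, in
#'   (0, 1).
#' @param rho Reversion probability per deviating site per sampled passage.
#' @param x_multiplier Multiplier on the chrX de novo rate in XX lines.
#' @param x_active_passages Number of leading sampled passages during which
#'   chrX de novo events occur (the X instability window).
#' @param x_reversion Reversion probability for chrX deviations.
#' @param r_parent Parent-line de novo probability per eligible probe per
#'   sampled passage (no decay, no reversion).
#' @param n_imprint Number of imprinted loci (autosomal, expected beta 0.5).
#' @param imprint_aberrant_lines Number of iPSC lines carrying a fixed
#'   hyper-methylated first imprint locus.
#' @param imprint_global_locus Plant one imprint locus hyper-methylated in
#'   every sample (all roles)?
#' @param imprint_beta Beta level of aberrant imprint loci.
#' @param expression_fold Expression fold change of stem-regulated genes.
#' @param expression_noise_sd SD of log-normal expression noise.
#' @param set_sex Optional character vector of per-set sexes (XX/XY).
#' @param seed Integer seed governing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 25000L,
                       n_parent_sets = 5L,
                       lines_per_set = c(5L, 5L, 4L, 4L, 4L),
                       esc_lines = 5L,
                       passages = c(13L, 18L, 31L, 39L),
                       parent_passages = c(5L, 11L, 16L),
                       frac_island = 0.7,
                       island_frac_ss_hypo = 0.85,
                       island_frac_ss_hyper = 0.3,
                       frac_chrX = 0.04,
                       frac_methylated = 0.3,
                       mu0 = 0.1,
                       mu1 = 0.9,
                       noise_sd = 0.05,
                       theta = 0.3,
                       high_cut = 0.6,
                       n_ss_hyper = 174L,
                       n_ss_hypo = 46L,
                       n_parent_specific = 800L,
                       memory_pool = 200L,
                       n_inherited = 120L,
                       frac_parent_hyper = 0.5,
                       r_denovo = 0.009,
                       gamma = 0.5,
                       rho = 0.5,
                       x_multiplier = 8,
                       x_active_passages = 2L,
                       x_reversion = 1,
                       r_parent = 0.002,
                       n_imprint = 87L,
                       imprint_aberrant_lines = 6L,
                       imprint_global_locus = TRUE,
                       imprint_beta = 0.9,
                       expression_fold = 10,
                       expression_noise_sd = 0.2,
                       set_sex = NULL,
                       seed = 20110526L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_parent_sets = as.integer(n_parent_sets),
              lines_per_set = as.integer(rep_len(lines_per_set, n_parent_sets)),
              esc_lines = as.integer(esc_lines),
              passages = as.integer(passages),
              parent_passages = as.integer(parent_passages),
              frac_island = frac_island,
              island_frac_ss_hypo = island_frac_ss_hypo,
              island_frac_ss_hyper = island_frac_ss_hyper,
              frac_chrX = frac_chrX,
              frac_methylated = frac_methylated,
              mu0 = mu0, mu1 = mu1,
              noise_sd = noise_sd,
              theta = theta, high_cut = high_cut,
              n_ss_hyper = as.integer(n_ss_hyper),
              n_ss_hypo = as.integer(n_ss_hypo),
              n_parent_specific = as.integer(n_parent_specific),
              memory_pool = as.integer(memory_pool),
              n_inherited = as.integer(n_inherited),
              frac_parent_hyper = frac_parent_hyper,
              r_denovo = r_denovo, gamma = gamma, rho = rho,
              x_multiplier = x_multiplier,
              x_active_passages = as.integer(x_active_passages),
              x_reversion = x_reversion,
              r_parent = r_parent,
              n_imprint = as.integer(n_imprint),
              imprint_aberrant_lines = as.integer(imprint_aberrant_lines),
              imprint_global_locus = isTRUE(imprint_global_locus),
              imprint_beta = imprint_beta,
              expression_fold = expression_fold,
              expression_noise_sd = expression_noise_sd,
              set_sex = set_sex,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (nm in c("frac_island", "island_frac_ss_hypo", "island_frac_ss_hyper",
               "frac_chrX", "frac_methylated", "r_denovo", "rho",
               "x_reversion", "r_parent", "frac_parent_hyper")) {
    assert_scalar_prob(cfg[[nm]], nm)
  }
  assert_scalar_prob(cfg$gamma, "gamma", lo_open = TRUE, hi_open = FALSE)
  if (cfg$mu0 >= cfg$mu1) abort("mu0 must be < mu1")
  if (cfg$mu0 < 0 || cfg$mu1 > 1) abort("mu0/mu1 must lie in [0, 1]")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (is.unsorted(cfg$passages, strictly = TRUE)) abort("passages must be strictly increasing")
  if (is.unsorted(cfg$parent_passages, strictly = TRUE)) {
    abort("parent_passages must be strictly increasing")
  }
  planted <- cfg$n_ss_hyper + cfg$n_ss_hypo + cfg$n_imprint +
    cfg$n_parent_sets * cfg$n_parent_specific
  if (planted > cfg$n_probes) {
    abort(sprintf("infeasible config: %d planted sites exceed %d probes",
                  planted, cfg$n_probes))
  }
  if (cfg$memory_pool > cfg$n_parent_specific) abort("memory_pool exceeds n_parent_specific")
  if (cfg$n_inherited > cfg$memory_pool) abort("n_inherited exceeds memory_pool")
  if (cfg$imprint_aberrant_lines > sum(cfg$lines_per_set)) {
    abort("imprint_aberrant_lines exceeds total iPSC lines")
  }
  if (!is.null(cfg$set_sex)) {
    if (length(cfg$set_sex) != cfg$n_parent_sets ||
        !all(cfg$set_sex %in% c("XX", "XY"))) {
      abort("set_sex must give XX/XY per parent set")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Configuration mirroring the study conditions
#'
#' Alias of [sim_config()] with all defaults: the conditions under which the
#' qualitative reprogramming patterns (hyper-methylation bias above 70%,
#' decreasing ES-iPS-DMR totals and de novo counts, XX-specific transient
#' chrX aberrations, non-decreasing parent drift) emerge.
#'
#' @return A `sim_config` list.
#' @export
default_paperlike_config <- function() sim_config()

sim_set_names <- function(cfg) {
  n <- cfg$n_parent_sets
  if (n <= length(DEFAULT_SET_NAMES)) DEFAULT_SET_NAMES[seq_len(n)]
  else c(DEFAULT_SET_NAMES, paste0("Set", seq_len(n - length(DEFAULT_SET_NAMES)) +
                                     length(DEFAULT_SET_NAMES)))
}

sim_set_sex <- function(cfg, set_names) {
  if (!is.null(cfg$set_sex)) return(stats::setNames(cfg$set_sex, set_names))
  sex <- ifelse(set_names %in% names(DEFAULT_SET_SEX),
                DEFAULT_SET_SEX[set_names],
                rep_len(c("XX", "XY"), length(set_names)))
  stats::setNames(sex, set_names)
}

#' Simulate a longitudinal methylation dataset
#'
#' Draws a complete dataset -- beta matrix, sample sheet, probe annotation,
#' expression table -- from the stochastic reprogramming model, together
#' with a ground-truth object holding probe labels, per-line inherited-site
#' lists, the full de novo gain / reversion event log, the noiseless base
#' matrix and the noise draws. All randomness flows from `cfg$seed`;
#' identical configurations give bit-identical output.
#'
#' Model outline: ESC lines scatter around a fixed reference landscape.
#' Parent lines differ from it at the planted stem-cell-specific sites and
#' at their own parent-specific sites, and drift further away by gaining
#' (never losing) de novo methylation with passaging. iPSC lines start at
#' the stem-cell state except for inherited parent-state sites, then at each
#' sampled passage revert deviating sites toward the ESC level with
#' probability `rho` and gain de novo hyper-methylation among unmethylated
#' background probes with a geometrically decaying rate -- amplified on chrX
#' in XX lines during the first `x_active_passages` passages, with chrX
#' deviations reverting at `x_reversion`. Imprint loci sit at 0.5 except for
#' planted fixed aberrations that never revert.
#'
#' @param cfg A [sim_config()].
#' @return A `methyl_sim` list: `beta` ([beta_matrix()]), `sample_sheet`,
#'   `annotation`, `expression`, `truth` (see Details), `config`.
#' @export
simulate_methylation <- function(cfg = sim_config()) {
  cfg <- validate_sim_config(unclass(cfg))
  withr::with_seed(cfg$seed, simulate_methylation_impl(cfg))
}

simulate_methylation_impl <- function(cfg) {
  n <- cfg$n_probes
  probe_id <- sprintf("cg%08d", seq_len(n))
  set_names <- sim_set_names(cfg)
  set_sex <- sim_set_sex(cfg, set_names)

  chromosome <- sample(c(as.character(1:22), "X"), n, replace = TRUE,
                       prob = c(rep((1 - cfg$frac_chrX) / 22, 22), cfg$frac_chrX))
  autosomal <- which(chromosome != "X")

  # planted probe roles (disjoint)
  imprint_idx <- sort(sample(autosomal, cfg$n_imprint))
  remaining <- setdiff(seq_len(n), imprint_idx)
  ss_hyper_idx <- sort(sample(remaining, cfg$n_ss_hyper))
  remaining <- setdiff(remaining, ss_hyper_idx)
  ss_hypo_idx <- sort(sample(remaining, cfg$n_ss_hypo))
  remaining <- setdiff(remaining, ss_hypo_idx)
  ps_idx <- list()
  for (s in set_names) {
    ps_idx[[s]] <- sort(sample(remaining, cfg$n_parent_specific))
    remaining <- setdiff(remaining, ps_idx[[s]])
  }
  pool_idx <- lapply(ps_idx, function(ix) ix[seq_len(cfg$memory_pool)])

  label <- rep("background", n)
  label[ss_hyper_idx] <- "ss_hyper"
  label[ss_hypo_idx] <- "ss_hypo"
  label[imprint_idx] <- "imprint"
  ps_set <- rep(NA_character_, n)
  for (s in set_names) {
    label[ps_idx[[s]]] <- "parent_specific"
    ps_set[ps_idx[[s]]] <- s
  }

  cpg_island <- stats::runif(n) < cfg$frac_island
  cpg_island[ss_hypo_idx] <- stats::runif(length(ss_hypo_idx)) < cfg$island_frac_ss_hypo
  cpg_island[ss_hyper_idx] <- stats::runif(length(ss_hyper_idx)) < cfg$island_frac_ss_hyper

  gene_symbol <- sprintf("GENE%05d", seq_len(n))
  imprint_names <- c("MEG3", "H19", sprintf("IMPR%03d", seq_len(max(cfg$n_imprint - 2, 0)) + 2))
  gene_symbol[imprint_idx] <- imprint_names[seq_len(cfg$n_imprint)]

  # ESC reference landscape (the stem-cell state)
  parent_hyper <- rep(NA, n)
  parent_hyper[label == "parent_specific"] <-
    stats::runif(sum(label == "parent_specific")) < cfg$frac_parent_hyper
  esc_ref <- ifelse(stats::runif(n) < cfg$frac_methylated, cfg$mu1, cfg$mu0)
  esc_ref[ss_hyper_idx] <- cfg$mu1
  esc_ref[ss_hypo_idx] <- cfg$mu0
  esc_ref[label == "parent_specific" & parent_hyper] <- cfg$mu0
  esc_ref[label == "parent_specific" & !parent_hyper] <- cfg$mu1
  esc_ref[imprint_idx] <- 0.5
  global_imprint <- if (cfg$imprint_global_locus && cfg$n_imprint >= 2) imprint_idx[2] else integer()
  esc_ref[global_imprint] <- cfg$imprint_beta

  # parent base state per set
  parent_base <- function(s) {
    st <- esc_ref
    st[ss_hyper_idx] <- cfg$mu0
    st[ss_hypo_idx] <- cfg$mu1
    ix <- ps_idx[[s]]
    st[ix] <- ifelse(parent_hyper[ix], cfg$mu1, cfg$mu0)
    st
  }

  ipsc_lines <- unlist(lapply(seq_along(set_names), function(i) {
    paste0(set_names[i], "_iPS_", seq_len(cfg$lines_per_set[i]))
  }))
  line_set <- stats::setNames(rep(set_names, cfg$lines_per_set), ipsc_lines)
  meg3_aberrant <- sort(sample(ipsc_lines, cfg$imprint_aberrant_lines))
  meg3_idx <- if (cfg$n_imprint >= 1) imprint_idx[1] else integer()

  events <- list()
  inherited_tbl <- list()
  cols <- list()
  col_meta <- list()
  add_col <- function(id, base, line, role, set, sex, passage) {
    cols[[id]] <<- base
    col_meta[[id]] <<- tibble(sample_id = id, line_name = line, role = role,
                              parent_set = set, sex = sex,
                              passage = as.integer(passage))
  }

  # ESC samples
  esc_sex <- rep_len(c("XX", "XY"), cfg$esc_lines)
  for (i in seq_len(cfg$esc_lines)) {
    add_col(paste0("ESC_", i), esc_ref, paste0("ESC_", i), "ESC",
            NA_character_, esc_sex[i], NA)
  }

  is_x <- chromosome == "X"
  eligible_bg <- label == "background" & esc_ref == cfg$mu0

  # parent lines: drift by gains only (rate r_parent, no decay, no reversion)
  for (s in set_names) {
    line <- paste0(s, "_parent")
    state <- parent_base(s)
    for (k in seq_along(cfg$parent_passages)) {
      p <- cfg$parent_passages[k]
      if (k >= 2) {
        elig <- which(eligible_bg & state == esc_ref)
        gained <- elig[stats::runif(length(elig)) < cfg$r_parent]
        if (length(gained)) {
          state[gained] <- cfg$mu1
          events[[length(events) + 1]] <- tibble(line = line, passage = p,
                                                 probe_id = probe_id[gained],
                                                 event = "gain")
        }
      }
      add_col(paste0(line, "_P", p), state, line, "parent", s, set_sex[[s]], p)
    }
  }

  # iPSC lines
  for (line in ipsc_lines) {
    s <- line_set[[line]]
    sex <- set_sex[[s]]
    inherited <- sort(sample(pool_idx[[s]], cfg$n_inherited))
    inherited_tbl[[line]] <- tibble(line = line, probe_id = probe_id[inherited])
    state <- esc_ref
    state[inherited] <- ifelse(parent_hyper[inherited], cfg$mu1, cfg$mu0)
    if (length(meg3_idx) && line %in% meg3_aberrant) state[meg3_idx] <- cfg$imprint_beta
    for (k in seq_along(cfg$passages)) {
      p <- cfg$passages[k]
      just_reverted <- integer()
      if (k >= 2) {
        deviant <- which(label != "imprint" & state != esc_ref)
        if (length(deviant)) {
          rev_p <- ifelse(is_x[deviant], cfg$x_reversion, cfg$rho)
          reverted <- deviant[stats::runif(length(deviant)) < rev_p]
          if (length(reverted)) {
            state[reverted] <- esc_ref[reverted]
            just_reverted <- reverted
            events[[length(events) + 1]] <- tibble(line = line, passage = p,
                                                   probe_id = probe_id[reverted],
                                                   event = "reversion")
          }
        }
      }
      rate <- rep(cfg$r_denovo * cfg$gamma^(k - 1), n)
      if (k <= cfg$x_active_passages) {
        if (sex == "XX") rate[is_x] <- rate[is_x] * cfg$x_multiplier
      } else {
        rate[is_x] <- 0
      }
      rate <- pmin(rate, 1)
      elig <- which(eligible_bg & state == esc_ref)
      elig <- setdiff(elig, just_reverted)
      gained <- elig[stats::runif(length(elig)) < rate[elig]]
      if (length(gained)) {
        state[gained] <- cfg$mu1
        events[[length(events) + 1]] <- tibble(line = line, passage = p,
                                               probe_id = probe_id[gained],
                                               event = "gain")
      }
      add_col(paste0(line, "_P", p), state, line, "iPSC", s, sex, p)
    }
  }

  base <- do.call(cbind, cols)
  rownames(base) <- probe_id
  noise <- matrix(if (cfg$noise_sd > 0) stats::rnorm(length(base), 0, cfg$noise_sd) else 0,
                  nrow = nrow(base), ncol = ncol(base), dimnames = dimnames(base))
  beta <- clamp01(base + noise)

  sheet <- dplyr::bind_rows(col_meta)
  ann <- tibble(probe_id = probe_id, gene_symbol = gene_symbol,
                chromosome = chromosome, cpg_island = cpg_island)
  bm <- beta_matrix(dplyr::bind_cols(tibble(probe_id = probe_id),
                                     as_tibble(as.data.frame(beta))))

  # expression: ss-hypo genes high in stem samples, ss-hyper genes low
  genes <- gene_symbol
  mult <- rep(1, n)
  mult[ss_hypo_idx] <- cfg$expression_fold
  mult[ss_hyper_idx] <- 1 / cfg$expression_fold
  stem_cols <- sheet$sample_id[sheet$role %in% c("ESC", "iPSC")]
  expr_mat <- matrix(100, n, nrow(sheet), dimnames = list(genes, sheet$sample_id))
  expr_mat[, stem_cols] <- expr_mat[, stem_cols] * mult
  expr_mat <- expr_mat * exp(matrix(stats::rnorm(length(expr_mat), 0, cfg$expression_noise_sd),
                                    nrow = n))
  expression <- dplyr::bind_cols(tibble(gene = genes),
                                 as_tibble(as.data.frame(expr_mat)))

  imprint_truth <- tibble(
    locus = gene_symbol[imprint_idx],
    probe_id = probe_id[imprint_idx],
    expected = 0.5,
    scope = dplyr::case_when(
      imprint_idx %in% meg3_idx ~ "line-aberrant",
      imprint_idx %in% global_imprint ~ "global-aberrant",
      TRUE ~ "normal"
    ),
    aberrant_lines = ifelse(imprint_idx %in% meg3_idx,
                            paste(meg3_aberrant, collapse = ","), "")
  )

  truth <- list(
    labels = tibble(probe_id = probe_id, label = label, parent_set = ps_set,
                    memory_pool = seq_len(n) %in% unlist(pool_idx),
                    parent_hyper = parent_hyper),
    esc_ref = stats::setNames(esc_ref, probe_id),
    inherited = dplyr::bind_rows(inherited_tbl),
    events = if (length(events)) dplyr::bind_rows(events) else
      tibble(line = character(), passage = integer(),
             probe_id = character(), event = character()),
    imprint = imprint_truth,
    base_beta = base,
    noise = noise
  )

  structure(list(beta = bm, sample_sheet = sheet, annotation = ann,
                 expression = expression, truth = truth, config = cfg),
            class = "methyl_sim")
}

#' @export
print.methyl_sim <- function(x, ...) {
  cat(sprintf(paste0("# methyl_sim: %d probes x %d samples ",
                     "(%d ESC, %d parent, %d iPSC samples; seed %d)\n"),
              nrow(x$beta), ncol(x$beta) - 1L,
              sum(x$sample_sheet$role == "ESC"),
              sum(x$sample_sheet$role == "parent"),
              sum(x$sample_sheet$role == "iPSC"),
              x$config$seed))
  invisible(x)
}

#' Reconstruct the noiseless base matrix from the ground truth
#'
#' Replays the event log against the planted structure (ESC reference,
#' inherited sites, imprint aberrations) and returns the noiseless beta
#' matrix it implies. Agreement with `truth$base_beta` certifies that the
#' event log is a complete account of the emitted data.
#'
#' @param sim A `methyl_sim` from [simulate_methylation()].
#' @return Numeric matrix matching `sim$truth$base_beta`.
#' @export
replay_events <- function(sim) {
  stopifnot(inherits(sim, "methyl_sim"))
  cfg <- sim$config
  truth <- sim$truth
  probe_id <- truth$labels$probe_id
  esc_ref <- unname(truth$esc_ref[probe_id])
  out <- matrix(NA_real_, length(probe_id), nrow(sim$sample_sheet),
                dimnames = list(probe_id, sim$sample_sheet$sample_id))
  parent_state_at <- function(ix) ifelse(truth$labels$parent_hyper[ix], cfg$mu1, cfg$mu0)

  for (ln in unique(sim$sample_sheet$line_name)) {
    rows <- sim$sample_sheet[sim$sample_sheet$line_name == ln, ]
    role <- rows$role[1]
    if (role == "ESC") {
      out[, rows$sample_id] <- esc_ref
      next
    }
    if (role == "parent") {
      state <- esc_ref
      ss <- truth$labels$label %in% c("ss_hyper", "ss_hypo")
      state[truth$labels$label == "ss_hyper"] <- cfg$mu0
      state[truth$labels$label == "ss_hypo"] <- cfg$mu1
      own <- which(truth$labels$label == "parent_specific" &
                     truth$labels$parent_set == rows$parent_set[1])
      state[own] <- parent_state_at(own)
    } else {
      state <- esc_ref
      inh <- match(truth$inherited$probe_id[truth$inherited$line == ln], probe_id)
      state[inh] <- parent_state_at(inh)
      ab <- truth$imprint[truth$imprint$scope == "line-aberrant", ]
      for (i in seq_len(nrow(ab))) {
        if (ln %in% strsplit(ab$aberrant_lines[i], ",")[[1]]) {
          state[match(ab$probe_id[i], probe_id)] <- cfg$imprint_beta
        }
      }
    }
    ev <- truth$events[truth$events$line == ln, ]
    for (p in sort(unique(rows$passage))) {
      step <- ev[ev$passage == p, ]
      rev_ix <- match(step$probe_id[step$event == "reversion"], probe_id)
      state[rev_ix] <- esc_ref[rev_ix]
      gain_ix <- match(step$probe_id[step$event == "gain"], probe_id)
      state[gain_ix] <- cfg$mu1
      out[, rows$sample_id[rows$passage == p]] <- state
    }
  }
  out
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `beta_matrix.tsv`, `sample_sheet.csv`, `probe_annotation.tsv`,
#' `expression.tsv` and `ground_truth.json` (labels, inherited sites, event
#' log and imprint table; the numeric base/noise matrices are reproducible
#' from the seed and are not serialised).
#'
#' @param sim A `methyl_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "methyl_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(sim$beta, file.path(dir, "beta_matrix.tsv"))
  write_sample_sheet(sim$sample_sheet, file.path(dir, "sample_sheet.csv"))
  write_probe_annotation(sim$annotation, file.path(dir, "probe_annotation.tsv"))
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"), progress = FALSE)
  gt <- list(config = unclass(sim$config),
             labels = sim$truth$labels,
             inherited = sim$truth$inherited,
             events = sim$truth$events,
             imprint = sim$truth$imprint)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(dir)
}
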