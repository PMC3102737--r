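# small in-code fixtures shared across test files

# beta_matrix from a plain numeric matrix (rows = probes, cols = samples)
toy_beta <- function(mat, probes = sprintf("p%02d", seq_len(nrow(mat))),
                     samples = sprintf("s%d", seq_len(ncol(mat))),
                     detection_p = NULL) {
  tb <- tibble::as_tibble(as.data.frame(mat))
  names(tb) <- samples
  if (!is.null(detection_p)) dimnames(detection_p) <- list(probes, samples)
  beta_matrix(dplyr::bind_cols(tibble::tibble(probe_id = probes), tb),
              detection_p = detection_p)
}

random_beta <- function(n_probes, n_samples, seed) {
  withr::with_seed(seed, {
    toy_beta(matrix(round(stats::runif(n_probes * n_samples), 4),
                    n_probes, n_samples))
  })
}

# quick profile constructor
mp <- function(beta, probes = sprintf("p%02d", seq_along(beta)), label = "prof") {
  methylation_profile(probes, beta, label = label)
}

# a small, fast simulation used where full scale is not needed
small_sim <- function(seed = 11, ...) {
  args <- list(n_probes = 2000, n_parent_sets = 3, lines_per_set = 2,
               n_ss_hyper = 20, n_ss_hypo = 8, n_parent_specific = 80,
               memory_pool = 30, n_inherited = 15, n_imprint = 6,
               imprint_aberrant_lines = 2, seed = seed)
  args <- utils::modifyList(args, list(...))
  simulate_methylation(do.call(sim_config, args))
}
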