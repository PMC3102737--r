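# Deliberately naive reference implementations (plain loops, explicit
# enumeration) used as independent oracles. They must stay independent of
# the package code paths they check.

# per-probe group mean with optional all-pairs intra-group exclusion
oracle_group_average <- function(mat, theta, intra_exclude, require_complete = TRUE) {
  out <- rep(NA_real_, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    obs <- v[!is.na(v)]
    if (!length(obs)) next
    if (require_complete && length(obs) < length(v)) next
    drop <- FALSE
    if (intra_exclude && length(obs) >= 2) {
      for (a in seq_along(obs)) {
        for (b in seq_along(obs)) {
          if (a < b && abs(obs[a] - obs[b]) >= theta) drop <- TRUE
        }
      }
    }
    if (!drop) out[i] <- mean(obs)
  }
  out
}

# called probes between two beta vectors, with direction
oracle_call <- function(av, bv, probes, theta) {
  res <- list()
  for (i in seq_along(probes)) {
    if (is.na(av[i]) || is.na(bv[i])) next
    d <- av[i] - bv[i]
    if (abs(d) >= theta) {
      res[[length(res) + 1]] <- data.frame(probe_id = probes[i], delta = d,
                                           direction = if (d > 0) "hyper" else "hypo")
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(probe_id = character(), delta = numeric(), direction = character())
}

# category of one probe from its three membership flags, written as the
# explicit eight-way enumeration
oracle_category <- function(ep, ip, ei) {
  if (!ep && !ip && !ei) return("none")
  if (ep && !ip && !ei) return("aa")
  if (!ep && ip && ei) return("bb")
  if (!ep && ip && !ei) return("cc")
  if (!ep && !ip && ei) return("dd")
  if (ep && ip && !ei) return("ee")
  if (ep && !ip && ei) return("ff")
  "gg"
}

# inherited/aberrant/unresolved class of one called site
oracle_site_class <- function(b_line, b_parent, theta) {
  if (is.na(b_parent)) return("unresolved")
  if (abs(b_line - b_parent) < theta) "inherited" else "aberrant"
}

# first-appearance cohorts from an explicit probe x passage incidence matrix
oracle_cohorts <- function(called) {
  first <- rep(NA_integer_, nrow(called))
  for (i in seq_len(nrow(called))) {
    for (j in seq_len(ncol(called))) {
      if (called[i, j] && is.na(first[i])) first[i] <- j
    }
  }
  first
}
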