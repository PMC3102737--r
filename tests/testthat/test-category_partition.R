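# helper: build a triad of dmr_calls over a fixed universe by giving the
# desired membership pattern directly through constructed profiles
triad_from_pattern <- function(in_ep, in_ip, in_ei) {
  n <- length(in_ep)
  probes <- sprintf("p%02d", seq_len(n))
  # parent at 0.5; ESC and iPSC levels grid-searched to realise each
  # membership bit exactly:
  # in_ep: |esc - parent| >= .3 ; in_ip: |ips - parent| >= .3 ; in_ei: |esc - ips| >= .3
  cand <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  esc <- ips <- numeric(n)
  for (i in seq_len(n)) {
    found <- FALSE
    for (e in cand) {
      for (v in cand) {
        if ((abs(e - 0.5) >= 0.3) == in_ep[i] &&
            (abs(v - 0.5) >= 0.3) == in_ip[i] &&
            (abs(e - v) >= 0.3) == in_ei[i]) {
          esc[i] <- e; ips[i] <- v; found <- TRUE; break
        }
      }
      if (found) break
    }
    stopifnot(found)
  }
  parent <- rep(0.5, n)
  list(d_ep = call_dmrs(mp(esc, probes, label = "ESC"), mp(parent, probes, label = "par")),
       d_ip = call_dmrs(mp(ips, probes, label = "iPS"), mp(parent, probes, label = "par")),
       d_ei = call_dmrs(mp(esc, probes, label = "ESC"), mp(ips, probes, label = "iPS")))
}

test_that("the seven-category partition matches the truth-table enumeration", {
  # all 8 membership patterns, twice over, in scrambled order
  pats <- expand.grid(ep = c(FALSE, TRUE), ip = c(FALSE, TRUE), ei = c(FALSE, TRUE))
  pats <- rbind(pats, pats[c(5, 3, 8, 1, 7, 2, 6, 4), ])
  tri <- triad_from_pattern(pats$ep, pats$ip, pats$ei)
  tab <- partition_categories(tri$d_ep, tri$d_ip, tri$d_ei, parent_set = "toy")
  expect_equal(nrow(tab), 16L)
  expected <- mapply(oracle_category, pats$ep, pats$ip, pats$ei)
  expect_identical(tab$category, unname(expected))
  # anchor cases
  expect_identical(tab$category[tab$in_ep & tab$in_ip & !tab$in_ei][1], "ee")
  expect_identical(tab$category[!tab$in_ep & !tab$in_ip & !tab$in_ei][1], "none")
  expect_identical(tab$category[tab$in_ep & tab$in_ip & tab$in_ei][1], "gg")
  # partition property: one category per probe, levels restricted
  expect_true(all(tab$category %in% c("none", "aa", "bb", "cc", "dd", "ee", "ff", "gg")))
  expect_equal(anyDuplicated(tab$probe_id), 0L)
})

test_that("partitioning rejects mismatched universes and thresholds", {
  tri <- triad_from_pattern(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, TRUE))
  other <- call_dmrs(mp(c(0.9, 0, 0), sprintf("q%d", 1:3)),
                     mp(c(0, 0, 0), sprintf("q%d", 1:3)))
  expect_error(partition_categories(tri$d_ep, tri$d_ip, other), "universe")
  tight <- call_dmrs(mp(c(0.9, 0), sprintf("p%02d", 1:2)),
                     mp(c(0, 0), sprintf("p%02d", 1:2)), theta = 0.5)
  expect_error(partition_categories(tri$d_ep, tri$d_ip, tight), "thresholds")
})

test_that("stem cell-specific and -required DMRs follow set algebra", {
  # hand-built category tables for three parent sets
  mk <- function(set, ee_probes, dir = "hyper") {
    tibble::tibble(parent_set = set,
                   probe_id = sprintf("p%02d", 1:10),
                   category = ifelse(sprintf("p%02d", 1:10) %in% ee_probes, "ee", "none"),
                   in_ep = FALSE, in_ip = FALSE, in_ei = FALSE,
                   direction_ip = ifelse(sprintf("p%02d", 1:10) %in% ee_probes,
                                         dir, NA_character_))
  }
  tables <- dplyr::bind_rows(
    mk("A", c("p01", "p02", "p05")),
    mk("B", c("p01", "p02", "p07")),
    mk("C", c("p01", "p05", "p07", "p02")))
  ss <- stem_cell_specific_dmrs(tables)
  expect_setequal(ss$probe_id, c("p01", "p02")) # intersection only
  req <- stem_cell_required_dmrs(tables)
  expect_setequal(req$probe_id, c("p01", "p02", "p05", "p07")) # union
  expect_equal(req$n_sets[req$probe_id == "p05"], 2L)
  expect_equal(req$parent_sets[req$probe_id == "p07"], "B,C")
  # ss is always a subset of required
  expect_true(all(ss$probe_id %in% req$probe_id))
  # a probe missing from one set's ee drops out of the intersection
  expect_false("p05" %in% ss$probe_id)
  expect_error(stem_cell_specific_dmrs(mk("A", "p01")), ">= 2 parent sets")
})

test_that("planted stem-cell sites are recovered and bb/ff stay empty on synthetic data", {
  sim <- small_sim(seed = 5)
  cats <- categorize_parent_sets(sim$beta, sim$sample_sheet, theta = 0.3)
  # exactly one category per (set, probe)
  expect_equal(nrow(dplyr::distinct(cats, parent_set, probe_id)), nrow(cats))
  expect_true(all(table(cats$parent_set) == nrow(sim$beta)))
  # the iPSC-specific ("bb") and inherited ("ff") patterns never recur in
  # every parent set: their cross-set intersections are empty
  for (cat in c("bb", "ff")) {
    per_set <- split(cats$probe_id[cats$category == cat],
                     cats$parent_set[cats$category == cat])
    shared <- Reduce(intersect,
                     c(per_set, replicate(3 - length(per_set), character(),
                                          simplify = FALSE)))
    expect_length(shared, 0)
  }
  ss <- stem_cell_specific_dmrs(cats)
  truth <- sim$truth$labels
  planted <- sort(truth$probe_id[truth$label %in% c("ss_hyper", "ss_hypo")])
  expect_identical(sort(ss$probe_id), planted)
  dir_truth <- truth$label[match(ss$probe_id, truth$probe_id)]
  expect_identical(ss$direction, ifelse(dir_truth == "ss_hyper", "hyper", "hypo"))
})

test_that("composition fractions tally directions and island status", {
  probes <- tibble::tibble(probe_id = sprintf("p%02d", 1:20),
                           direction = rep(c("hyper", "hypo"), each = 10))
  ann <- tibble::tibble(probe_id = sprintf("p%02d", 1:20),
                        gene_symbol = sprintf("G%d", 1:20),
                        chromosome = "1",
                        cpg_island = rep(c(TRUE, FALSE), 10))
  comp <- composition_report(probes, ann)
  expect_equal(comp$fraction, c(0.5, 0.5))
  expect_equal(sum(comp$fraction), 1)
  all_island <- composition_report(probes, dplyr::mutate(ann, cpg_island = TRUE))
  expect_equal(all_island$island_fraction, c(1, 1))

  set <- withr::with_seed(13, dplyr::slice_sample(probes, n = 12))
  comp2 <- composition_report(set, ann)
  for (d in comp2$direction) {
    ids <- set$probe_id[set$direction == d]
    expect_equal(comp2$n[comp2$direction == d], length(ids))
    expect_equal(comp2$n_island[comp2$direction == d],
                 sum(ann$cpg_island[match(ids, ann$probe_id)]))
  }
})

test_that("expression integration classifies by group-mean fold change", {
  sheet <- tibble::tibble(
    sample_id = c("E1", "I1", "P1", "P2"),
    line_name = c("E1", "I1", "P", "P"),
    role = c("ESC", "iPSC", "parent", "parent"),
    parent_set = c(NA, "P", "P", "P"),
    sex = "XX", passage = NA_integer_)
  ann <- tibble::tibble(probe_id = sprintf("p%02d", 1:12),
                        gene_symbol = sprintf("G%02d", 1:12),
                        chromosome = "1", cpg_island = FALSE)
  probes <- tibble::tibble(probe_id = sprintf("p%02d", 1:12),
                           direction = rep(c("hypo", "hyper"), 6))
  stem <- withr::with_seed(2, round(runif(12, 10, 1000)))
  parent <- withr::with_seed(3, round(runif(12, 10, 1000)))
  stem[1] <- 600; parent[1] <- 100   # ratio 6 > 5 -> high
  stem[2] <- 100; parent[2] <- 100   # equal -> unclassified
  parent[3] <- 0                     # pseudocount path
  expr <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("G%02d", 1:12)),
    tibble::as_tibble(as.data.frame(cbind(E1 = stem, I1 = stem, P1 = parent, P2 = parent))))
  res <- integrate_expression(probes, expr, sheet, ann, fold = 5)
  expect_equal(res$expression_class[res$gene == "G01"], "high")
  expect_equal(res$expression_class[res$gene == "G02"], "unclassified")
  expect_equal(res$ratio[res$gene == "G03"], stem[3] / 1)
  # every class equals the direct ratio computation
  for (i in 1:12) {
    g <- sprintf("G%02d", i)
    r <- res[res$gene == g, ]
    sm <- if (stem[i] == 0) 1 else stem[i]
    pm <- if (parent[i] == 0) 1 else parent[i]
    want <- if (sm / pm > 5) "high" else if (pm / sm > 5) "low" else "unclassified"
    expect_equal(r$expression_class, want, info = g)
  }
  # absent gene -> unmeasured, not an error
  res2 <- integrate_expression(probes, expr[-1, ], sheet, ann, fold = 5)
  expect_equal(res2$expression_class[res2$gene == "G01"], "unmeasured")
})
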