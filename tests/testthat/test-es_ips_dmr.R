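test_that("ES-iPS-DMR calls split into inherited and aberrant correctly", {
  probes <- c("p01", "p02", "p03", "p04")
  line <- mp(c(0.9, 0.9, 0.5, 0.9), probes, label = "iPS-1")
  esc <- mp(c(0.2, 0.2, 0.5, 0.2), probes, label = "ESC")
  parent <- mp(c(0.85, 0.1, 0.5, 0.6), probes, label = "par")
  s <- call_es_ips_dmrs(line, esc, parent, theta = 0.3, passage = 13)
  # p01: differs from ESC by 0.7, matches parent within 0.05 -> inherited
  expect_equal(s$class[s$probe_id == "p01"], "inherited")
  # p02: differs from both -> aberrant
  expect_equal(s$class[s$probe_id == "p02"], "aberrant")
  # p03: no ESC difference -> not called
  expect_false("p03" %in% s$probe_id)
  # p04: parent difference exactly at threshold -> aberrant (inclusive tie)
  expect_equal(s$class[s$probe_id == "p04"], "aberrant")
  expect_equal(attr(s, "passage"), 13L)
  # inherited + aberrant + unresolved covers every call
  expect_true(all(s$class %in% c("inherited", "aberrant", "unresolved")))
})

test_that("missing parent yields unresolved classes", {
  line <- mp(c(0.9, 0.1))
  esc <- mp(c(0.2, 0.8))
  s <- call_es_ips_dmrs(line, esc, parent = NULL)
  expect_equal(nrow(s), 2L)
  expect_true(all(s$class == "unresolved"))
  # partially missing parent
  parent <- mp(c(NA, 0.75))
  s2 <- call_es_ips_dmrs(line, esc, parent)
  expect_equal(s2$class, c("unresolved", "aberrant"))
})

test_that("classification matches the brute-force two-comparison scan", {
  for (seed in c(4, 44)) {
    vals <- withr::with_seed(seed, matrix(runif(90), 30, 3))
    probes <- sprintf("p%02d", 1:30)
    s <- call_es_ips_dmrs(mp(vals[, 1], probes), mp(vals[, 2], probes),
                          mp(vals[, 3], probes), theta = 0.3)
    want_called <- probes[abs(vals[, 1] - vals[, 2]) >= 0.3]
    expect_setequal(s$probe_id, want_called)
    for (p in s$probe_id) {
      i <- match(p, probes)
      expect_equal(s$class[s$probe_id == p],
                   oracle_site_class(vals[i, 1], vals[i, 3], 0.3))
      expect_equal(s$direction[s$probe_id == p],
                   if (vals[i, 1] > vals[i, 2]) "hyper" else "hypo")
    }
  }
})

test_that("overlap spectra count line membership and conserve totals", {
  probes <- sprintf("p%02d", 1:12)
  mk_set <- function(ids) {
    line <- mp(ifelse(probes %in% ids, 0.9, 0.1), probes)
    call_es_ips_dmrs(line, mp(rep(0.1, 12), probes), theta = 0.3)
  }
  # explicit incidence: p01 in all 5, p02 in 3, p03 in 1
  sets <- list(mk_set(c("p01", "p02", "p03")),
               mk_set(c("p01", "p02")),
               mk_set(c("p01", "p02")),
               mk_set(c("p01")),
               mk_set(c("p01")))
  spec <- overlap_spectrum(sets)
  expect_equal(spec$n_probes[spec$k == 5], 1L)
  expect_equal(spec$n_probes[spec$k == 3], 1L)
  expect_equal(spec$n_probes[spec$k == 1], 1L)
  expect_equal(sum(spec$n_probes), 3L)
  # conservation: sum(k * count) equals total membership across lines
  expect_equal(sum(spec$k * spec$n_probes),
               sum(vapply(sets, nrow, integer(1))))
  expect_identical(probes_with_min_overlap(spec, 3), c("p01", "p02"))
  expect_identical(probes_with_min_overlap(spec, 5), "p01")
  # randomised case against an explicit incidence matrix
  inc <- withr::with_seed(9, matrix(runif(12 * 5) < 0.4, 12, 5))
  rsets <- lapply(1:5, function(j) mk_set(probes[inc[, j]]))
  rspec <- overlap_spectrum(rsets)
  counts <- rowSums(inc)
  for (k in 1:5) expect_equal(rspec$n_probes[rspec$k == k], sum(counts == k))
})

test_that("stratification produces complete, consistent contingency counts", {
  probes <- sprintf("p%02d", 1:10)
  ann <- tibble::tibble(probe_id = probes, gene_symbol = probes,
                        chromosome = rep("2", 10), cpg_island = rep(c(TRUE, FALSE), 5))
  sheet <- tibble::tibble(sample_id = "L1_P5", line_name = "L1", role = "iPSC",
                          parent_set = "P", sex = "XX", passage = 5L) |>
    dplyr::bind_rows(tibble::tibble(sample_id = "P_P5", line_name = "P", role = "parent",
                                    parent_set = "P", sex = "XX", passage = 5L))
  line <- mp(c(rep(0.9, 8), rep(0.05, 2)), probes, label = "L1")
  esc <- mp(rep(0.4, 10), probes)
  s <- call_es_ips_dmrs(line, esc, parent = NULL, theta = 0.3, line_name = "L1")
  strat <- stratify_dmrs(list(s), ann, sheet)
  # all DMRs on chr2 -> zero on X
  expect_equal(sum(strat$n[strat$chrom_class == "X"]), 0L)
  # marginal equals the call-set size
  expect_equal(sum(strat$n), nrow(s))
  # 8 hyper of 10 -> fraction 0.8
  expect_equal(sum(strat$n[strat$direction == "hyper"]) / sum(strat$n), 0.8)
  # the autosome/X grid is complete
  expect_equal(nrow(strat), 2 * 3 * 2 * 2)
})

test_that("XX lines show the elevated chrX burden the generator plants", {
  sim <- small_sim(seed = 23)
  x <- sim$beta; sheet <- sim$sample_sheet
  esc <- group_average(x, sheet$sample_id[sheet$role == "ESC"], theta = 0.3)
  ipsc <- sheet[sheet$role == "iPSC", ]
  first_p <- min(ipsc$passage)
  early <- ipsc[ipsc$passage == first_p, ]
  sets <- lapply(seq_len(nrow(early)), function(i) {
    call_es_ips_dmrs(sample_profile(x, early$sample_id[i]), esc,
                     line_name = early$line_name[i], passage = first_p)
  })
  strat <- stratify_dmrs(sets, sim$annotation, sheet)
  ss <- sex_summary(strat)
  expect_gt(ss$mean_chrx_dmrs[ss$sex == "XX"], ss$mean_chrx_dmrs[ss$sex == "XY"])
})
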