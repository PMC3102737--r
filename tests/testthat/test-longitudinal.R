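# build a per-passage series of es_ips_dmrs from an explicit incidence
# matrix (probes x passages): called sites get beta 0.9 vs ESC 0.1
series_from_incidence <- function(called, passages, probes = sprintf("p%02d", seq_len(nrow(called)))) {
  esc <- mp(rep(0.1, nrow(called)), probes, label = "ESC")
  lapply(seq_along(passages), function(j) {
    line <- mp(ifelse(called[, j], 0.9, 0.1), probes, label = "L1")
    call_es_ips_dmrs(line, esc, theta = 0.3, line_name = "L1", passage = passages[j])
  })
}

test_that("cohorts are assigned at first appearance with correct survival", {
  passages <- c(13L, 18L, 31L, 39L)
  called <- matrix(FALSE, 3, 4)
  called[1, ] <- c(TRUE, TRUE, FALSE, FALSE)  # appears P13, survives P18, gone
  called[2, ] <- c(FALSE, FALSE, FALSE, TRUE) # appears only at the last passage
  called[3, ] <- c(TRUE, FALSE, TRUE, FALSE)  # reappears after a gap
  track <- build_cohorts(series_from_incidence(called, passages))
  t1 <- track[track$probe_id == "p01", ]
  expect_true(all(t1$first_passage == 13))
  expect_equal(t1$called, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unique(track$first_passage[track$probe_id == "p02"]), 39L)
  # reappearance does not open a new cohort
  expect_equal(unique(track$first_passage[track$probe_id == "p03"]), 13L)
})

test_that("cohort tables equal the brute-force first-appearance walk", {
  passages <- c(4L, 13L, 22L, 40L)
  called <- withr::with_seed(31, matrix(runif(40 * 4) < 0.3, 40, 4))
  keep <- rowSums(called) > 0
  track <- build_cohorts(series_from_incidence(called, passages))
  first <- oracle_cohorts(called)
  probes <- sprintf("p%02d", 1:40)
  expect_setequal(unique(track$probe_id), probes[keep])
  for (p in unique(track$probe_id)) {
    i <- match(p, probes)
    expect_equal(unique(track$first_passage[track$probe_id == p]),
                 passages[first[i]])
    expect_equal(track$called[track$probe_id == p], called[i, ])
  }
  # cohort partition: every ever-called probe in exactly one cohort
  one <- dplyr::distinct(track, probe_id, first_passage)
  expect_equal(anyDuplicated(one$probe_id), 0L)
  # survival sets are subsets of their cohort, with survival(p, p) = cohort(p)
  for (p in passages) {
    cohort <- one$probe_id[one$first_passage == p]
    expect_setequal(track$probe_id[track$called & track$first_passage == p &
                                     track$passage == p], cohort)
    for (q in passages[passages > p]) {
      surv <- track$probe_id[track$called & track$first_passage == p &
                               track$passage == q]
      expect_true(all(surv %in% cohort))
    }
  }
})

test_that("survival counts are non-increasing when sites do not reappear", {
  passages <- c(10L, 20L, 30L, 40L)
  called <- matrix(FALSE, 30, 4)
  # monotone disappearance: each probe stays called for a while, then stops
  withr::with_seed(7, {
    start <- sample(1:4, 30, replace = TRUE)
    stop_at <- pmin(start + sample(0:3, 30, replace = TRUE), 4)
  })
  for (i in 1:30) called[i, start[i]:stop_at[i]] <- TRUE
  track <- build_cohorts(series_from_incidence(called, passages))
  for (p in passages) {
    surv <- vapply(passages[passages >= p], function(q) {
      sum(track$called & track$first_passage == p & track$passage == q)
    }, integer(1))
    expect_true(length(surv) < 2 || all(diff(surv) <= 0))
  }
})

test_that("cohort building rejects malformed series", {
  passages <- c(13L, 18L)
  called <- matrix(TRUE, 2, 2)
  series <- series_from_incidence(called, passages)
  expect_error(build_cohorts(series[1]), ">= 2 passages")
  expect_error(build_cohorts(series[c(2, 1)]), "strictly increasing")
  expect_error(build_cohorts(series[c(1, 1)]), "duplicate passages")
})

test_that("convergence summaries flag decreasing totals and de novo counts", {
  # totals 286 -> 194 -> 110 -> 55 across four passages
  passages <- c(13L, 18L, 31L, 39L)
  n <- 286 + 66 + 29 + 16
  called <- matrix(FALSE, n, 4)
  called[1:286, 1] <- TRUE; called[1:194, 2] <- TRUE
  called[1:110, 3] <- TRUE; called[1:55, 4] <- TRUE
  called[287:352, 2] <- TRUE   # 66 de novo at P18
  called[353:381, 3] <- TRUE   # 29 de novo at P31
  called[382:397, 4] <- TRUE   # 16 de novo at P39
  summ <- convergence_summary(build_cohorts(series_from_incidence(called, passages)))
  expect_equal(summ$total, c(286L, 194L + 66L, 110L + 29L, 55L + 16L))
  expect_equal(summ$de_novo, c(NA, 66L, 29L, 16L))
  flags <- attr(summ, "flags")
  expect_true(flags$decreasing_total)
  expect_true(flags$de_novo_nonincreasing)

  # constant totals -> no convergence
  const <- matrix(TRUE, 30, 4)
  f2 <- attr(convergence_summary(build_cohorts(series_from_incidence(const, passages))),
             "flags")
  expect_false(f2$decreasing_total)
})

test_that("difference values subtract the ESC score with sign meaning hyper", {
  probes <- sprintf("p%02d", 1:5)
  esc <- mp(rep(0.5, 5), probes)
  same <- list(`10` = mp(rep(0.5, 5), probes))
  dp0 <- difference_profile(same, esc, probes)
  expect_true(all(dp0$delta == 0))
  extreme <- list(`10` = mp(rep(1, 5), probes))
  esc0 <- mp(rep(0, 5), probes)
  dp1 <- difference_profile(extreme, esc0, probes)
  expect_true(all(dp1$delta == 1))
  expect_error(difference_profile(same, esc, c(probes, "zz")), "outside the universe")
})

test_that("transient hyper-methylation converges toward zero on synthetic data", {
  sim <- small_sim(seed = 3)
  x <- sim$beta; sheet <- sim$sample_sheet
  esc <- group_average(x, sheet$sample_id[sheet$role == "ESC"], theta = 0.3)
  ln <- sheet$line_name[sheet$role == "iPSC"][1]
  rows <- dplyr::arrange(sheet[sheet$line_name == ln, ], passage)
  series <- stats::setNames(lapply(rows$sample_id, function(s) sample_profile(x, s)),
                            rows$passage)
  sets <- lapply(seq_len(nrow(rows)), function(i) {
    call_es_ips_dmrs(sample_profile(x, rows$sample_id[i]), esc,
                     line_name = ln, passage = rows$passage[i])
  })
  track <- build_cohorts(sets)
  first_cohort <- unique(track$probe_id[track$first_passage == rows$passage[1]])
  dsum <- difference_summary(difference_profile(series, esc, first_cohort))
  # early deviations are predominantly hyper-methylated, then fade
  expect_gt(dsum$frac_positive[1], 0.5)
  expect_lt(dsum$mean_abs_delta[nrow(dsum)], dsum$mean_abs_delta[1])
})

test_that("parent lines drift away from the ESC profile without converging", {
  probes <- sprintf("p%02d", 1:6)
  esc <- mp(rep(0.1, 6), probes)
  same <- mp(rep(0.1, 6), probes)
  flat <- parent_drift(list(`5` = same, `11` = same, `16` = same), esc)
  expect_equal(flat$total, c(0L, 0L, 0L))
  expect_true(attr(flat, "flags")$nondecreasing_total)
  expect_error(parent_drift(list(`5` = same), esc), ">= 2 passages")

  sim <- small_sim(seed = 3)
  x <- sim$beta; sheet <- sim$sample_sheet
  esc_avg <- group_average(x, sheet$sample_id[sheet$role == "ESC"], theta = 0.3)
  parents <- sheet[sheet$role == "parent" & sheet$line_name == "UtE_parent", ]
  parents <- dplyr::arrange(parents, passage)
  series <- stats::setNames(lapply(parents$sample_id, function(s) sample_profile(x, s)),
                            parents$passage)
  drift <- parent_drift(series, esc_avg, line_name = "UtE_parent")
  expect_true(attr(drift, "flags")$nondecreasing_total)
  expect_gt(drift$total[nrow(drift)], 0)
})

test_that("the imprint screen flags deviations from the biallelic level", {
  loci <- tibble::tibble(probe_id = c("p01", "p02", "p03"),
                         locus = c("MEG3", "H19", "IMPR003"),
                         expected = 0.5)
  profiles <- list(
    L1 = mp(c(0.5, 0.95, 0.5), c("p01", "p02", "p03")),
    L2 = mp(c(0.12, 0.5, NA), c("p01", "p02", "p03")),
    L3 = mp(c(0.5, 0.5), c("p01", "p02")))
  rep <- imprint_report(profiles, loci)
  expect_equal(rep$status[rep$line == "L1" & rep$locus == "MEG3"], "normal")
  expect_equal(rep$status[rep$line == "L1" & rep$locus == "H19"], "hyper-aberrant")
  expect_equal(rep$status[rep$line == "L2" & rep$locus == "MEG3"], "hypo-aberrant")
  expect_equal(rep$status[rep$line == "L2" & rep$locus == "IMPR003"], "unmeasured")
  expect_equal(rep$status[rep$line == "L3" & rep$locus == "IMPR003"], "unmeasured")
  # grid equals the direct threshold scan
  for (i in seq_len(nrow(rep))) {
    r <- rep[i, ]
    if (r$status == "unmeasured") next
    want <- if (abs(r$beta - 0.5) < 0.3) "normal" else if (r$beta > 0.5)
      "hyper-aberrant" else "hypo-aberrant"
    expect_equal(r$status, want)
  }
})
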