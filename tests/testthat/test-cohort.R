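test_that("CAA burden sums grade to the published categories", {
  expect_equal(grade_caa_burden(0), "none")
  expect_equal(grade_caa_burden(c(1, 4)), c("mild", "mild"))
  expect_equal(grade_caa_burden(c(5, 8)), c("moderate", "moderate"))
  expect_equal(grade_caa_burden(c(9, 12)), c("severe", "severe"))
  expect_error(grade_caa_burden(13), "0-12")
  expect_error(grade_caa_burden(-1), "0-12")
  expect_error(grade_caa_burden(2.5), "0-12")
})

test_that("fixture reproduces the published marginal counts exactly", {
  fix <- fixture_cohort()
  expect_equal(nrow(fix), 62L)
  expect_equal(sum(fix$outcome), 36L)
  g0 <- fix[fix$outcome == 0, ]; g1 <- fix[fix$outcome == 1, ]
  expect_equal(c(sum(g0$sah), sum(g1$sah)), c(11L, 32L))
  expect_equal(c(sum(g0$apoe_e4), sum(g1$apoe_e4)), c(2L, 18L))
  expect_equal(c(sum(g0$flp), sum(g1$flp)), c(0L, 14L))
  expect_equal(c(sum(g0$apoe_e2), sum(g1$apoe_e2)), c(3L, 11L))
  expect_equal(c(sum(g0$anticoagulant_use), sum(g1$anticoagulant_use)), c(4L, 5L))
  expect_equal(c(sum(g0$strictly_lobar), sum(g1$strictly_lobar)), c(22L, 36L))
  expect_equal(c(sum(g0$sex == "M"), sum(g1$sex == "M")), c(12L, 11L))
})

test_that("fixture joint cells honour the published accuracy statistics", {
  fix <- fixture_cohort()
  g1 <- fix[fix$outcome == 1, ]
  # no case lacks both SAH and e4 (100% rule-out sensitivity)
  expect_equal(sum(g1$sah == 0 & g1$apoe_e4 == 0), 0L)
  # exactly one control is rule-in positive (96% = 25/26 specificity)
  g0 <- fix[fix$outcome == 0, ]
  expect_equal(sum(g0$sah == 1 & (g0$apoe_e4 == 1 | g0$flp == 1)), 1L)
  # 23 rule-in positives among cases (LR+ 16.6)
  expect_equal(sum(g1$sah == 1 & (g1$apoe_e4 == 1 | g1$flp == 1)), 23L)
  # burden grading consistent with outcome
  expect_equal(fix$outcome,
               as.integer(grade_caa_burden(fix$caa_burden_sum) %in%
                            c("moderate", "severe")))
})

test_that("cohort validation enforces the schema invariants", {
  fix <- as.data.frame(fixture_cohort())
  dup <- fix; dup$id[2] <- dup$id[1]
  expect_error(caa_cohort(dup), "unique")
  bad <- fix; bad$sah[1] <- 2
  expect_error(caa_cohort(bad), "binary")
  miss <- fix[setdiff(names(fix), "flp")]
  expect_error(caa_cohort(miss), "flp")
  incons <- fix; incons$outcome[1] <- 1L  # burden sum 0 says outcome 0
  expect_error(caa_cohort(incons), "inconsistent")
})

test_that("CSV round trip is identity for all provenance classes", {
  check_roundtrip <- function(cohort) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_cohort_csv(cohort, f)
    back <- read_cohort_csv(f)
    a <- as.data.frame(cohort); b <- as.data.frame(back)
    expect_identical(names(a), names(b))
    for (nm in names(a)) expect_identical(a[[nm]], b[[nm]])
  }
  check_roundtrip(fixture_cohort())
  check_roundtrip(simulate_cohort(simulation_config(
    "logistic", n = 40, pattern_probs = rep(1 / 8, 8),
    beta = c(-1, 1, 1, 1), seed = 1)))
  # optional columns absent: only the core schema round-trips
  small <- caa_cohort(data.frame(id = c("a", "b", "c"), outcome = c(0, 1, 0),
                                 apoe_e4 = c(0, 1, 0), sah = c(1, 1, 0),
                                 flp = c(0, 1, 0)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(small, f)
  expect_identical(names(read_cohort_csv(f)), names(small))
})

test_that("shipped fixture CSV loads to the 62-participant cohort", {
  path <- system.file("extdata", "edinburgh_cohort_synthetic.csv",
                      package = "caadx")
  coh <- read_cohort_csv(path)
  expect_equal(nrow(coh), 62L)
  expect_equal(sum(coh$outcome), 36L)
})

test_that("CSV reader normalises binaries, derives outcome, reports errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,caa_burden_sum,apoe_e4,sah,flp",
               "a,0,yes,TRUE,0", "b,7,no,false,1", "c,10,0,1,Yes"), f)
  coh <- read_cohort_csv(f)
  expect_equal(coh$outcome, c(0L, 1L, 1L))      # derived from burden sums
  expect_equal(coh$apoe_e4, c(1L, 0L, 0L))
  expect_equal(coh$sah, c(1L, 0L, 1L))
  expect_equal(coh$flp, c(0L, 1L, 1L))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,outcome,apoe_e4,sah", "a,1,0,1"), f2)
  expect_error(read_cohort_csv(f2), "flp")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("", f3)
  expect_error(read_cohort_csv(f3), "empty|parse")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,outcome,apoe_e4,sah,flp", "a,1,0,1,0", "b,1,maybe,0,0"), f4)
  expect_error(read_cohort_csv(f4), "row 2")

  # column mapping resolves non-canonical headers
  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,outcome,e4,subarachnoid,projections", "a,1,0,1,0", "b,0,1,0,0"), f5)
  coh5 <- read_cohort_csv(f5, col_map = c(apoe_e4 = "e4", sah = "subarachnoid",
                                          flp = "projections"))
  expect_equal(coh5$sah, c(1L, 0L))
})

test_that("simulator is seed-deterministic in both modes", {
  cfg_l <- simulation_config("logistic", n = 200, pattern_probs = rep(1 / 8, 8),
                             beta = c(-2.55, 3.11, 2.31, 3.20), seed = 11)
  expect_identical(as.data.frame(simulate_cohort(cfg_l)),
                   as.data.frame(simulate_cohort(cfg_l)))
  fp <- c(14, 0, 10, 0, 1, 0, 1, 0) / 26
  cp <- c(0, 0, 9, 9, 4, 0, 9, 5) / 36
  cfg_c <- simulation_config("conditional", n_per_group = c(50, 50),
                             pattern_probs_0 = fp, pattern_probs_1 = cp,
                             seed = 11)
  expect_identical(as.data.frame(simulate_cohort(cfg_c)),
                   as.data.frame(simulate_cohort(cfg_c)))
})

test_that("simulated pattern frequencies converge to the configured law", {
  # chi-square goodness of fit non-rejection at alpha = 0.001, 20 seeds
  probs <- c(0.25, 0.05, 0.2, 0.1, 0.15, 0.05, 0.1, 0.1)
  pvals <- vapply(1:20, function(s) {
    coh <- simulate_cohort(simulation_config(
      "logistic", n = 1e5, pattern_probs = probs,
      beta = c(0, 0, 0, 0), seed = s))
    idx <- 1L + 4L * coh$apoe_e4 + 2L * coh$sah + coh$flp
    stats::chisq.test(tabulate(idx, 8L), p = probs)$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("logistic-mode outcome rate matches the model probability", {
  coh <- simulate_cohort(simulation_config(
    "logistic", n = 62000, pattern_probs = rep(1 / 8, 8),
    beta = c(-2.55, 3.11, 2.31, 3.20), seed = 4))
  none <- coh$apoe_e4 == 0 & coh$sah == 0 & coh$flp == 0
  expect_equal(mean(coh$outcome[none]), 0.072, tolerance = 0.1)
  # empirical pattern frequencies within 0.01 of configured
  idx <- 1L + 4L * coh$apoe_e4 + 2L * coh$sah + coh$flp
  expect_true(all(abs(tabulate(idx, 8L) / nrow(coh) - 1 / 8) < 0.01))
})

test_that("simulation config rejects invalid probability vectors", {
  expect_error(simulation_config("logistic", n = 10,
                                 pattern_probs = rep(1 / 7, 7),
                                 beta = rep(0, 4)), "probabilities")
  expect_error(simulation_config("logistic", n = 10,
                                 pattern_probs = c(rep(1 / 8, 7), 0.2),
                                 beta = rep(0, 4)), "summing to 1")
  expect_error(simulation_config("conditional", n_per_group = c(0, 5),
                                 pattern_probs_0 = rep(1 / 8, 8),
                                 pattern_probs_1 = rep(1 / 8, 8)), ">= 1")
})

test_that("filter_cohort excludes matching rows and keeps order", {
  fix <- fixture_cohort()
  kept <- filter_cohort(fix, anticoagulant_use == 1)
  expect_equal(nrow(kept), 53L)
  expect_equal(attr(kept, "n_removed"), 9L)
  expect_false(is.unsorted(match(kept$id, fix$id)))

  none <- filter_cohort(fix, sah == 2)
  expect_equal(nrow(none), 62L)
  expect_equal(attr(none, "n_removed"), 0L)

  all_gone <- filter_cohort(fix, outcome %in% c(0, 1))
  expect_equal(nrow(all_gone), 0L)
  expect_equal(attr(all_gone, "n_removed"), 62L)

  expect_error(filter_cohort(fix, nonesuch == 1), "unknown field")
})
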