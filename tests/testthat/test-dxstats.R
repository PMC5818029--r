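# Published contingency tables are oriented (row 1: absent/mild CAA,
# row 2: moderate/severe CAA) x (feature present, feature absent).

test_that("Woolf odds ratios reproduce the published univariable estimates", {
  e4 <- odds_ratio_woolf(c(2, 24, 18, 18))
  expect_equal(round(e4$or, 2), 12.00)
  expect_equal(round(e4$lower, 2), 2.46)
  expect_equal(round(e4$upper, 2), 58.47)
  expect_equal(e4$method, "woolf")

  sah <- odds_ratio_woolf(c(11, 15, 32, 4))
  expect_equal(round(sah$or, 2), 10.91)
  expect_equal(round(sah$lower, 2), 2.98)
  expect_equal(round(sah$upper, 2), 39.96)

  flp <- odds_ratio_woolf(c(0, 26, 14, 22))
  expect_equal(round(flp$or, 2), 34.16)
  expect_equal(round(flp$lower, 2), 1.93)
  expect_equal(flp$upper, 605.23, tolerance = 1e-3)
  expect_true(flp$zero_cell)
  expect_equal(flp$method, "woolf_haldane")
})

test_that("zero-cell policy: NA marker and degenerate margins", {
  flp_na <- odds_ratio_woolf(c(0, 26, 14, 22), zero_cell = "na")
  expect_true(is.na(flp_na$or))
  expect_equal(flp_na$method, "na")
  # whole zero column is undefined under either policy
  expect_true(is.na(odds_ratio_woolf(c(0, 10, 0, 10))$or))
  sym <- odds_ratio_woolf(c(5, 5, 5, 5))
  expect_equal(sym$or, 1)
  expect_true(sym$lower < 1 && sym$upper > 1)
})

test_that("Haldane-corrected Woolf OR equals the univariable Firth OR", {
  set.seed(77)
  for (r in 1:100) {
    cells <- rpois(4, 6)
    if (r <= 30) cells[sample(4, 1)] <- 0  # include zero-cell tables
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    if (length(unique(c(rep(1, a + cc), rep(0, b + d)))) < 2) next
    fit <- fit_firth(expand_2x2(a, b, cc, d), predictors = "x")
    firth_or <- exp(coef(fit)[["x"]])
    expect_equal(firth_or, haldane_or(a, b, cc, d),
                 tolerance = 1e-6)
  }
})

test_that("continuity-corrected Wilson bounds match the published CIs", {
  expect_equal(round(100 * wilson_cc_interval(36, 36)[1, ]),
               c(lower = 88, upper = 100))
  expect_equal(round(100 * unname(wilson_cc_interval(25, 26)[1, "lower"])), 78)
  expect_equal(round(100 * wilson_cc_interval(32, 36)[1, ]),
               c(lower = 73, upper = 96))
  expect_equal(round(100 * unname(wilson_cc_interval(26, 26)[1, "lower"])), 84)
  expect_equal(unname(wilson_cc_interval(0, 10)[1, "lower"]), 0)
  expect_equal(unname(wilson_cc_interval(10, 10)[1, "upper"]), 1)
  expect_error(wilson_cc_interval(1, 0), "n must be")
  expect_error(wilson_cc_interval(5, 4), "0..n")
})

test_that("Wilson CC interval always contains k/n and narrows with n", {
  for (n in c(5, 20, 80)) for (k in 0:n) {
    ci <- wilson_cc_interval(k, n)
    expect_true(ci[1, "lower"] <= k / n && k / n <= ci[1, "upper"])
  }
  w <- function(k, n) diff(wilson_cc_interval(k, n)[1, ])
  expect_lt(w(90, 100), w(9, 10))
  expect_lt(w(50, 100), w(5, 10))
})

test_that("Wilson CC interval is conservative (coverage >= nominal)", {
  set.seed(202)
  k <- rbinom(1e5, 30, 0.9)
  ci <- wilson_cc_interval(k, 30)
  covered <- ci[, "lower"] <= 0.9 & 0.9 <= ci[, "upper"]
  expect_gte(mean(covered), 0.95)
})

test_that("accuracy report reproduces the published criteria statistics", {
  # rule-in on the fixture: TP 23, FP 1, FN 13, TN 25
  ri <- accuracy_stats(c(23, 1, 13, 25))
  expect_equal(round(ri$specificity[["estimate"]], 2), 0.96)
  expect_equal(round(ri$lr_pos[["estimate"]], 1), 16.6)
  expect_equal(round(100 * ri$specificity[["lower"]]), 78)
  # rule-out: test positive = not ruled out; TP 36, FP 12, FN 0, TN 14
  ro <- accuracy_stats(c(36, 12, 0, 14))
  expect_equal(ro$sensitivity[["estimate"]], 1)
  expect_equal(round(100 * ro$sensitivity[["lower"]]), 88)
  expect_equal(ro$lr_neg[["estimate"]], 0)
  # perfect test
  perfect <- accuracy_stats(c(10, 0, 0, 10))
  expect_equal(perfect$sensitivity[["estimate"]], 1)
  expect_equal(perfect$specificity[["estimate"]], 1)
  expect_equal(perfect$ppv[["estimate"]], 1)
  expect_equal(perfect$npv[["estimate"]], 1)
  expect_true(is.infinite(perfect$lr_pos[["estimate"]]))
  expect_error(accuracy_stats(c(0, 5, 0, 5)), "disease strata")
})

test_that("likelihood-ratio identities hold wherever defined", {
  set.seed(55)
  for (r in 1:50) {
    m <- matrix(rpois(4, 8) + 1, 2)
    acc <- accuracy_stats(m)
    sens <- acc$sensitivity[["estimate"]]; spec <- acc$specificity[["estimate"]]
    if (spec < 1)
      expect_equal(acc$lr_pos[["estimate"]], sens / (1 - spec))
    expect_equal(acc$lr_neg[["estimate"]], (1 - sens) / spec)
  }
})

test_that("Pearson chi-square reproduces the published p-values", {
  e4 <- pearson_chi2(c(2, 24, 18, 18))
  expect_equal(round(e4$statistic, 2), 12.37)
  expect_equal(round(e4$p, 4), 4e-04)
  flp <- pearson_chi2(c(0, 26, 14, 22))
  expect_equal(round(flp$p, 4), 3e-04)
  indep <- pearson_chi2(c(10, 10, 10, 10))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p, 1)
  expect_error(pearson_chi2(c(0, 0, 5, 5)), "zero margin")
})

test_that("Fisher test reproduces published values and the enumeration oracle", {
  expect_equal(round(fisher_exact(c(4, 22, 0, 36)), 3), 0.027)
  expect_equal(round(fisher_exact(c(4, 22, 5, 31)), 2), 1.00)
  set.seed(66)
  for (r in 1:100) {
    m <- matrix(rpois(4, 5), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m), fisher_oracle(t(m)), tolerance = 1e-10)
  }
})

test_that("test chooser follows the expected-count rule from the data", {
  e2 <- auto_association_test(c(3, 23, 11, 25))
  expect_equal(e2$test, "chi2")
  expect_equal(round(e2$p, 3), 0.077)
  dem <- auto_association_test(c(2, 24, 8, 28))
  expect_equal(dem$test, "fisher")
  expect_equal(round(dem$p, 2), 0.17)
  bal <- auto_association_test(c(10, 10, 10, 10))
  expect_equal(bal$p, 1)
})

test_that("Mann-Whitney: exact small-sample and approximate branches", {
  ident <- mann_whitney(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(ident$p, 1)
  sep <- mann_whitney(1:5, 6:10)
  expect_equal(sep$method, "exact")
  expect_equal(sep$p, 2 / choose(10, 5))
  # exact branch agrees with wilcox.test's own exact computation
  set.seed(88)
  x <- rnorm(6); y <- rnorm(7) + 0.5
  expect_equal(mann_whitney(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
  big <- mann_whitney(rnorm(30), rnorm(25))
  expect_equal(big$method, "normal approximation")
})

test_that("Cohen's kappa: limits, independence, and a worked ordinal example", {
  r <- c(1, 2, 3, 1, 2, 3, 1, 2)
  expect_equal(cohen_kappa(r, r)$kappa, 1)
  set.seed(99)
  a <- sample(1:3, 4000, replace = TRUE)
  b <- sample(1:3, 4000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.05)
  # worked 3x3 ordinal example, hand computation of weighted agreement
  r1 <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 2)
  r2 <- c(0, 1, 1, 2, 2, 2, 0, 0, 1, 2)
  k <- length(unique(c(r1, r2)))
  W <- 1 - abs(outer(1:k, 1:k, "-")) / (k - 1)
  O <- table(factor(r1, 0:2), factor(r2, 0:2)) / 10
  E <- outer(rowSums(O), colSums(O))
  po <- sum(W * O); pe <- sum(W * E)
  expect_equal(cohen_kappa(r1, r2, weights = "linear")$kappa,
               (po - pe) / (1 - pe))
  # unweighted differs from linear on off-diagonal disagreement
  expect_false(isTRUE(all.equal(cohen_kappa(r1, r2)$kappa,
                                cohen_kappa(r1, r2, "linear")$kappa)))
  expect_error(cohen_kappa(rep(1, 5), rep(1, 5)), "one category")
})

test_that("ICC(A,1): limits and the mean-squares oracle", {
  m <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(icc(m)$icc, 1)
  shifted <- cbind(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
  expect_lt(icc(shifted)$icc, 1)
  # worked matrix against a direct mean-squares decomposition
  w <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  n <- 6; k <- 2
  aov_df <- data.frame(y = c(w), subject = factor(rep(1:n, k)),
                       rater = factor(rep(1:k, each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, aov_df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expect_equal(icc(w)$icc,
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
  expect_error(icc(cbind(rep(1, 4), rep(1, 4))), "variance")
})

test_that("summary table reproduces the published predictor rows exactly", {
  fix <- fixture_cohort()
  t1 <- build_table1(fix, c(sah = "binary", apoe_e4 = "binary",
                            flp = "binary", anticoagulant_use = "binary",
                            age_years = "continuous"))
  sah <- t1[t1$variable == "sah", ]
  expect_equal(sah$group0, "11 (42%)")
  expect_equal(sah$group1, "32 (89%)")
  expect_equal(sah$or_display, "10.91 (2.98–39.96)")
  e4 <- t1[t1$variable == "apoe_e4", ]
  expect_equal(e4$or_display, "12.00 (2.46–58.47)")
  flp <- t1[t1$variable == "flp", ]
  expect_equal(round(flp$odds_ratio, 2), 34.16)
  expect_equal(flp$group1, "14 (39%)")
  ac <- t1[t1$variable == "anticoagulant_use", ]
  expect_equal(round(ac$p, 2), 1.00)
  age <- t1[t1$variable == "age_years", ]
  expect_equal(age$or_display, "NC")
  expect_equal(nrow(build_table1(fix, character(0) |>
                                   stats::setNames(character(0)))), 0L)
  expect_error(build_table1(fix, c(sah = "weird")), "unknown variable type")
  expect_error(build_table1(fix, c(nope = "binary")), "not in cohort")
})
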