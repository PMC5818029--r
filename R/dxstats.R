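# Contingency-table statistics: odds ratios, association tests, diagnostic
# accuracy with continuity-corrected Wilson intervals, likelihood ratios,
# rater agreement, and the cohort summary-table builder.

# coerce a 2x2 input (matrix or c(a,b,c,d) row-wise) to a numeric matrix
as_two_by_two <- function(tab) {
  if (is.numeric(tab) && length(tab) == 4L)
    tab <- matrix(tab, 2, 2, byrow = TRUE)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != floor(tab)))
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  if (sum(tab) < 1) stop("table total must be >= 1", call. = FALSE)
  storage.mode(tab) <- "numeric"
  tab
}

#' Woolf odds ratio for a 2x2 table
#'
#' Orientation: rows are the comparison groups (row 1 the reference group,
#' row 2 the index group), columns are feature present / absent. The odds
#' ratio is the odds of the feature in the index group over the reference
#' group, with the Woolf logit interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' Zero cells: with `zero_cell = "haldane"` one half is added to every cell
#' (Haldane-Anscombe) and the estimate is flagged; with `"na"` the estimate
#' is returned as `NA` (the convention of reporting "not available" when a
#' cell is zero). A whole zero row or column is undefined under either
#' policy.
#'
#' @param tab 2x2 matrix or `c(a, b, c, d)` row-wise.
#' @param zero_cell `"haldane"` or `"na"`.
#' @param level confidence level (default 0.95).
#' @return an `effect_estimate` list: `or`, `lower`, `upper`, `method`
#'   (`"woolf"`, `"woolf_haldane"` or `"na"`), `zero_cell` flag.
#' @examples
#' odds_ratio_woolf(c(2, 24, 18, 18))   # APOE e4: OR 12.00 (2.46-58.47)
#' @export
odds_ratio_woolf <- function(tab, zero_cell = c("haldane", "na"),
                             level = 0.95) {
  zero_cell <- match.arg(zero_cell)
  m <- as_two_by_two(tab)
  na_est <- function(reason) {
    structure(list(or = NA_real_, lower = NA_real_, upper = NA_real_,
                   method = "na", zero_cell = TRUE, reason = reason),
              class = "effect_estimate")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(na_est("a whole row or column is zero"))
  has_zero <- any(m == 0)
  if (has_zero) {
    if (zero_cell == "na") return(na_est("zero cell with policy 'na'"))
    m <- m + 0.5
  }
  or <- (m[2, 1] / m[2, 2]) / (m[1, 1] / m[1, 2])
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm((1 + level) / 2)
  structure(list(
    or = or, lower = or * exp(-z * se), upper = or * exp(z * se),
    method = if (has_zero) "woolf_haldane" else "woolf",
    zero_cell = has_zero
  ), class = "effect_estimate")
}

#' Wilson score interval with continuity correction
#'
#' The continuity-corrected Wilson interval for a binomial proportion,
#' truncated to `[0, 1]`; the lower bound is exactly 0 at `k = 0` and the
#' upper bound exactly 1 at `k = n`. This is the interval that reproduces
#' the published diagnostic-accuracy confidence bounds (e.g. a lower bound
#' of 88\% for 36/36 and 78\% for 25/26).
#'
#' @param k number of successes (vectorised).
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return matrix with columns `lower`, `upper`.
#' @examples
#' wilson_cc_interval(36, 36)
#' @export
wilson_cc_interval <- function(k, n, level = 0.95) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must be in 0..n", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  p <- k / n
  q <- 1 - p
  lower <- (2 * n * p + z^2 - 1 -
              z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) /
    (2 * (n + z^2))
  upper <- (2 * n * p + z^2 + 1 +
              z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) /
    (2 * (n + z^2))
  lower <- pmax(0, lower)
  upper <- pmin(1, upper)
  lower[p == 0] <- 0
  upper[p == 1] <- 1
  cbind(lower = lower, upper = upper)
}

#' Diagnostic accuracy of a binary test
#'
#' Input orientation: rows test positive / test negative, columns disease
#' present / absent, so `TP = tab[1,1]`, `FP = tab[1,2]`, `FN = tab[2,1]`,
#' `TN = tab[2,2]`. Proportions carry continuity-corrected Wilson intervals;
#' likelihood-ratio intervals use the log method
#' (`var(log LR+) = 1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN)`). `LR+` is flagged
#' infinite at specificity 1 and `LR- = 0` is permitted at sensitivity 1.
#'
#' @param tab 2x2 matrix or `c(TP, FP, FN, TN)`.
#' @param level confidence level.
#' @return an `accuracy_report` list with `sensitivity`, `specificity`,
#'   `ppv`, `npv` (each `(estimate, lower, upper)`), `lr_pos`, `lr_neg`
#'   (each `(estimate, lower, upper)`, possibly `Inf`/`NA`), and `table`.
#' @export
accuracy_stats <- function(tab, level = 0.95) {
  m <- as_two_by_two(tab)
  tp <- m[1, 1]; fp <- m[1, 2]; fn <- m[2, 1]; tn <- m[2, 2]
  if (tp + fn == 0 || fp + tn == 0)
    stop("both disease strata must be non-empty", call. = FALSE)
  prop <- function(k, n) {
    ci <- wilson_cc_interval(k, n, level)
    c(estimate = k / n, lower = unname(ci[1, "lower"]),
      upper = unname(ci[1, "upper"]))
  }
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  z <- stats::qnorm((1 + level) / 2)
  lr_ci <- function(est, se_terms) {
    if (!is.finite(est) || est == 0 || any(!is.finite(se_terms)))
      return(c(estimate = est, lower = NA_real_, upper = NA_real_))
    se <- sqrt(sum(se_terms))
    c(estimate = est, lower = est * exp(-z * se), upper = est * exp(z * se))
  }
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- (1 - sens) / spec
  structure(list(
    sensitivity = prop(tp, tp + fn),
    specificity = prop(tn, fp + tn),
    ppv = if (tp + fp > 0) prop(tp, tp + fp) else NULL,
    npv = if (fn + tn > 0) prop(tn, fn + tn) else NULL,
    lr_pos = lr_ci(lr_pos, c(1 / tp - 1 / (tp + fn), 1 / fp - 1 / (fp + tn))),
    lr_neg = lr_ci(lr_neg, c(1 / fn - 1 / (tp + fn), 1 / tn - 1 / (fp + tn))),
    table = m
  ), class = "accuracy_report")
}

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' `X2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param tab 2x2 matrix or `c(a, b, c, d)`.
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(tab) {
  m <- as_two_by_two(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square undefined: zero margin", call. = FALSE)
  n <- sum(m)
  stat <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    prod(c(rowSums(m), colSums(m)))
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Fisher's exact test (two-sided, point-probability definition)
#'
#' Sums hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table.
#'
#' @param tab 2x2 matrix or `c(a, b, c, d)`.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  m <- as_two_by_two(tab)
  stats::fisher.test(m)$p.value
}

#' Choose and run the appropriate association test for a 2x2 table
#'
#' Fisher's exact test when any expected cell count is below 5, otherwise the
#' Pearson chi-square test without continuity correction.
#'
#' @param tab 2x2 matrix or `c(a, b, c, d)`.
#' @return list with `test` (`"fisher"` or `"chi2"`), `p`, and `statistic`
#'   (`NA` for Fisher).
#' @export
auto_association_test <- function(tab) {
  m <- as_two_by_two(tab)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    list(test = "fisher", p = fisher_exact(m), statistic = NA_real_)
  } else {
    res <- pearson_chi2(m)
    list(test = "chi2", p = res$p, statistic = res$statistic)
  }
}

#' Mann-Whitney U test
#'
#' Exact enumeration for small untied samples (both sizes at most 8),
#' otherwise the tie-corrected normal approximation.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Cohen's kappa (unweighted or linear-weighted)
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with agreement weights
#' `w_ij = 1 - |i - j| / (k - 1)` for linear weighting over ordered
#' categories, identity weights otherwise. The reported standard error is the
#' large-sample approximation `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param ratings1,ratings2 paired ratings (factors or coercible); for linear
#'   weights the category order is the factor level order.
#' @param weights `"none"` or `"linear"`.
#' @return an `agreement_stats` list: `kappa`, `se`, `weights`.
#' @export
cohen_kappa <- function(ratings1, ratings2, weights = c("none", "linear")) {
  weights <- match.arg(weights)
  if (length(ratings1) != length(ratings2))
    stop("ratings must be paired", call. = FALSE)
  lev <- if (is.factor(ratings1) || is.factor(ratings2)) {
    union(levels(as.factor(ratings1)), levels(as.factor(ratings2)))
  } else sort(unique(c(ratings1, ratings2)))
  k <- length(lev)
  if (k < 2L)
    stop("kappa undefined: only one category observed", call. = FALSE)
  f1 <- factor(ratings1, levels = lev)
  f2 <- factor(ratings2, levels = lev)
  n <- length(f1)
  O <- table(f1, f2) / n
  marg1 <- rowSums(O); marg2 <- colSums(O)
  E <- outer(marg1, marg2)
  W <- if (weights == "linear") {
    1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  } else diag(k)
  po <- sum(W * O)
  pe <- sum(W * E)
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: expected agreement is 1", call. = FALSE)
  structure(list(
    kappa = (po - pe) / (1 - pe),
    se = sqrt(po * (1 - po) / (n * (1 - pe)^2)),
    weights = weights
  ), class = "agreement_stats")
}

#' Intraclass correlation coefficient (two-way, single measure, absolute
#' agreement)
#'
#' ICC(A,1) from the standard mean-squares decomposition of an
#' n subjects x k raters matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns.
#' @return an `agreement_stats` list: `icc`, `form`.
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings must have no missing values", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  if (stats::var(row_means) < 1e-24)
    stop("ICC undefined: no variance across subjects", call. = FALSE)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = val, form = "ICC(A,1) two-way single-measure absolute agreement"),
            class = "agreement_stats")
}

#' Build a two-group summary table
#'
#' One row per declared variable, split by outcome group: counts (integer
#' percentages) or median (IQR), a Woolf odds ratio for binary variables
#' (Haldane correction or "NA" per the zero-cell policy), and a p-value from
#' [auto_association_test()] (binary/ordinal) or [mann_whitney()]
#' (continuous).
#'
#' @param cohort a `caa_cohort` or data.frame with an `outcome` column.
#' @param variables named character vector of variable types, e.g.
#'   `c(sah = "binary", age_years = "continuous")`; ordinal variables are
#'   tested over their k x 2 table.
#' @param zero_cell zero-cell policy for odds ratios (per-table default).
#' @return data.frame with columns `variable`, `type`, `group0`, `group1`,
#'   `odds_ratio`, `or_lower`, `or_upper`, `or_display`, `p`, `test`.
#' @export
build_table1 <- function(cohort, variables,
                         zero_cell = c("haldane", "na")) {
  zero_cell <- match.arg(zero_cell)
  data <- as.data.frame(cohort)
  if (is.null(names(variables)) || any(!nzchar(names(variables))))
    stop("'variables' must be a named vector of types", call. = FALSE)
  bad_type <- setdiff(unique(variables), c("binary", "continuous", "ordinal"))
  if (length(bad_type))
    stop("unknown variable type(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(names(variables), names(data))
  if (length(miss))
    stop("variable(s) not in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  g0 <- data[data$outcome == 0, ]; g1 <- data[data$outcome == 1, ]
  rows <- lapply(names(variables), function(v) {
    type <- variables[[v]]
    if (type == "binary") {
      a <- sum(g0[[v]] == 1); b <- sum(g0[[v]] == 0)
      cc <- sum(g1[[v]] == 1); d <- sum(g1[[v]] == 0)
      est <- odds_ratio_woolf(c(a, b, cc, d), zero_cell = zero_cell)
      test <- auto_association_test(c(a, b, cc, d))
      data.frame(
        variable = v, type = type,
        group0 = fmt_count_pct(a, nrow(g0)),
        group1 = fmt_count_pct(cc, nrow(g1)),
        odds_ratio = est$or, or_lower = est$lower, or_upper = est$upper,
        or_display = fmt_or(est),
        p = test$p, test = test$test)
    } else if (type == "continuous") {
      mw <- mann_whitney(g0[[v]], g1[[v]])
      data.frame(
        variable = v, type = type,
        group0 = fmt_median_iqr(g0[[v]]), group1 = fmt_median_iqr(g1[[v]]),
        odds_ratio = NA_real_, or_lower = NA_real_, or_upper = NA_real_,
        or_display = "NC",
        p = mw$p, test = "mann_whitney")
    } else {
      lev <- sort(unique(data[[v]]))
      tab <- rbind(table(factor(g0[[v]], levels = lev)),
                   table(factor(g1[[v]], levels = lev)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      p <- if (any(expected < 5)) {
        stats::fisher.test(tab)$p.value
      } else {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
      data.frame(
        variable = v, type = type,
        group0 = paste(table(factor(g0[[v]], levels = lev)), collapse = "/"),
        group1 = paste(table(factor(g1[[v]], levels = lev)), collapse = "/"),
        odds_ratio = NA_real_, or_lower = NA_real_, or_upper = NA_real_,
        or_display = "..",
        p = p, test = "ordinal")
    }
  })
  if (length(rows) == 0L)
    return(data.frame(variable = character(0), type = character(0),
                      group0 = character(0), group1 = character(0),
                      odds_ratio = numeric(0), or_lower = numeric(0),
                      or_upper = numeric(0), or_display = character(0),
                      p = numeric(0), test = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# formatting helpers shared with the report renderer
fmt_count_pct <- function(k, n) sprintf("%d (%d%%)", k, round(100 * k / n))

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7)
  sprintf("%g (%g–%g)", round(q[2]), round(q[1]), round(q[3]))
}

fmt_or <- function(est) {
  if (est$method == "na" || !is.finite(est$or)) return("NA")
  sprintf("%.2f (%.2f–%.2f)", est$or, est$lower, est$upper)
}

fmt_p <- function(p) {
  ifelse(p < 1e-4, "<0.0001", sprintf("%.4g", signif(p, 2)))
}
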