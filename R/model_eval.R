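# Apparent performance, calibration, and bootstrap optimism-corrected
# internal validation (Harrell procedure).

check_two_classes <- function(outcomes) {
  if (length(unique(outcomes)) < 2L)
    stop("metric undefined: both outcome classes must be present",
         call. = FALSE)
}

#' Concordance (c) statistic
#'
#' Probability that a randomly chosen case receives a higher predicted
#' probability than a randomly chosen non-case, ties counted one half;
#' identical to the area under the ROC curve. Computed via midranks, so ties
#' are handled exactly.
#'
#' @param probs predicted probabilities.
#' @param outcomes binary outcomes (0/1).
#' @return scalar in `[0, 1]`.
#' @export
c_statistic <- function(probs, outcomes) {
  stopifnot(length(probs) == length(outcomes))
  check_two_classes(outcomes)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  r <- rank(probs)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile-bootstrap confidence interval for the c statistic
#'
#' @param probs,outcomes as in [c_statistic()].
#' @param B bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `c`, `lower`, `upper`, `B`.
#' @export
c_statistic_ci <- function(probs, outcomes, B = 2000L, seed = 1L,
                           level = 0.95) {
  est <- c_statistic(probs, outcomes)
  n <- length(probs)
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcomes[idx])) == 2L) break
    }
    c_statistic(probs[idx], outcomes[idx])
  }, numeric(1)))
  qs <- stats::quantile(reps, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
  list(c = est, lower = qs[1], upper = qs[2], B = B)
}

#' Nagelkerke's R-squared
#'
#' `R2_CS = 1 - exp(2 (l0 - l1) / n)` rescaled by its maximum
#' `1 - exp(2 l0 / n)`.
#'
#' @param loglik_model,loglik_null unpenalised log-likelihoods of the fitted
#'   and intercept-only models.
#' @param n sample size.
#' @return scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (loglik_model < loglik_null - 1e-8)
    stop("model log-likelihood below null log-likelihood", call. = FALSE)
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  r2_cs / (1 - exp(2 * loglik_null / n))
}

#' Brier score
#'
#' Mean squared difference between outcome and predicted probability.
#' @param probs predicted probabilities in `[0, 1]`.
#' @param outcomes binary outcomes.
#' @export
brier_score <- function(probs, outcomes) {
  stopifnot(length(probs) == length(outcomes), all(probs >= 0 & probs <= 1))
  mean((outcomes - probs)^2)
}

#' Discrimination slope
#'
#' Mean predicted probability among cases minus mean among non-cases.
#' @inheritParams c_statistic
#' @export
discrimination_slope <- function(probs, outcomes) {
  check_two_classes(outcomes)
  mean(probs[outcomes == 1]) - mean(probs[outcomes == 0])
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups are the distinct predicted-probability values when at most
#' `max_distinct` exist (a three-binary-predictor model yields at most 8,
#' typically 6 observed); otherwise deciles of risk. The statistic is
#' `sum((O - E)^2 / (E (1 - E / n_g)))` with `df = groups - 2`.
#'
#' @inheritParams c_statistic
#' @param max_distinct threshold for value-based grouping (default 10).
#' @return list with `statistic`, `df`, `p`, `groups` (a data.frame with
#'   per-group `n`, `predicted`, `observed`).
#' @export
hosmer_lemeshow <- function(probs, outcomes, max_distinct = 10L) {
  stopifnot(length(probs) == length(outcomes))
  uniq <- sort(unique(probs))
  if (length(uniq) <= max_distinct) {
    grp <- match(probs, uniq)
  } else {
    breaks <- unique(stats::quantile(probs, seq(0, 1, 0.1)))
    grp <- as.integer(cut(probs, breaks, include.lowest = TRUE))
  }
  g <- max(grp)
  if (g < 3L) stop("Hosmer-Lemeshow needs at least 3 groups", call. = FALSE)
  n_g <- tabulate(grp, g)
  O <- vapply(seq_len(g), function(k) sum(outcomes[grp == k]), numeric(1))
  E <- vapply(seq_len(g), function(k) sum(probs[grp == k]), numeric(1))
  contrib <- (O - E)^2 / (E * (1 - E / n_g))
  contrib[(O - E)^2 < 1e-24] <- 0  # exact agreement contributes nothing
  stat <- sum(contrib)
  df <- g - 2L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       groups = data.frame(n = n_g, predicted = E / n_g, observed = O / n_g))
}

#' ROC curve
#'
#' One point per distinct threshold (classifying positive when
#' `prob >= threshold`), plus the (0,0) endpoint. The trapezoidal area under
#' the returned polyline equals the c statistic to machine precision.
#'
#' @inheritParams c_statistic
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered from (0,0) to
#'   (1,1); attribute `"auc"` carries the trapezoidal area.
#' @export
roc_curve <- function(probs, outcomes) {
  check_two_classes(outcomes)
  thr <- sort(unique(probs), decreasing = TRUE)
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  tpr <- vapply(thr, function(t) sum(probs >= t & outcomes == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(probs >= t & outcomes == 0) / n0, numeric(1))
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) + utils::tail(out$tpr, -1)) / 2)
  attr(out, "auc") <- auc
  out
}

#' Apparent performance of a Firth model
#'
#' Bundles Nagelkerke R2, Brier score, AIC, c statistic (with optional
#' percentile-bootstrap CI), discrimination slope, Hosmer-Lemeshow test, ROC
#' points and calibration groups. The null log-likelihood for R2 is the
#' Bernoulli log-likelihood at the observed prevalence.
#'
#' @param fit a converged `firth_fit`.
#' @param c_ci if `TRUE`, add a percentile bootstrap CI for the c statistic.
#' @param B,seed bootstrap replicates and seed for the c statistic CI.
#' @return a `performance_metrics` list.
#' @export
performance_metrics <- function(fit, c_ci = FALSE, B = 2000L, seed = 1L) {
  stopifnot(inherits(fit, "firth_fit"))
  y <- fit$design$y
  probs <- fit$fitted
  n <- length(y)
  prev <- mean(y)
  ll0 <- n * (prev * log(prev) + (1 - prev) * log(1 - prev))
  hl <- hosmer_lemeshow(probs, y)
  out <- list(
    nagelkerke_r2 = nagelkerke_r2(fit$loglik_unpenalized, ll0, n),
    brier = brier_score(probs, y),
    aic = fit$aic,
    c_statistic = c_statistic(probs, y),
    discrimination_slope = discrimination_slope(probs, y),
    hosmer_lemeshow = hl[c("statistic", "df", "p")],
    roc = roc_curve(probs, y),
    calibration_groups = hl$groups,
    loglik_null = ll0
  )
  if (c_ci) out$c_statistic_ci <- c_statistic_ci(probs, y, B = B, seed = seed)
  class(out) <- "performance_metrics"
  out
}

# scalar metrics used in bootstrap validation, computed for a (probs, y)
# pair plus the log-likelihood pieces of the model producing probs
validation_metrics <- function(probs, y) {
  n <- length(y)
  prev <- mean(y)
  ll0 <- n * (prev * log(prev) + (1 - prev) * log(1 - prev))
  eta <- stats::qlogis(pmin(pmax(probs, 1e-12), 1 - 1e-12))
  ll1 <- bernoulli_loglik(eta, y)
  c(c_statistic = c_statistic(probs, y),
    nagelkerke_r2 = nagelkerke_r2(max(ll1, ll0), ll0, n),
    brier = brier_score(probs, y),
    discrimination_slope = discrimination_slope(probs, y))
}

#' Bootstrap optimism-corrected internal validation
#'
#' Harrell's procedure: draw `B` simple bootstrap resamples (with
#' replacement, full n), refit the Firth model on each, and evaluate each
#' refit both on its own resample ("boot") and on the original cohort
#' ("test"). Optimism is `mean(boot - test)` over converged replicates and
#' the corrected value is `apparent - optimism`. Firth penalisation keeps
#' resamples with separated predictors estimable. Replicates that fail to
#' fit (or lose an outcome class) are counted and excluded; more than 5\%
#' failures is an error.
#'
#' @param cohort a `caa_cohort` (or data.frame).
#' @param outcome,predictors model specification.
#' @param B bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param .indices optional list of index vectors overriding the resampler
#'   (for deterministic testing).
#' @return a `validation_report`: per-metric apparent / optimism / corrected,
#'   `B`, `seed`, `n_failed`.
#' @export
bootstrap_validate <- function(cohort, outcome = "outcome",
                               predictors = c("apoe_e4", "sah", "flp"),
                               B = 2000L, seed = 1L, .indices = NULL) {
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  data <- as.data.frame(cohort)
  fit0 <- fit_firth(data, outcome, predictors)
  apparent <- validation_metrics(fit0$fitted, data[[outcome]])
  n <- nrow(data)
  draw <- function(b) {
    if (!is.null(.indices)) .indices[[b]] else sample.int(n, n, replace = TRUE)
  }
  boot_mat <- matrix(NA_real_, B, length(apparent))
  test_mat <- matrix(NA_real_, B, length(apparent))
  n_failed <- 0L
  with_seed(seed, for (b in seq_len(B)) {
    idx <- draw(b)
    res <- tryCatch({
      dat_b <- data[idx, , drop = FALSE]
      fit_b <- fit_firth(dat_b, outcome, predictors)
      boot <- validation_metrics(fit_b$fitted, dat_b[[outcome]])
      test <- validation_metrics(predict(fit_b, data), data[[outcome]])
      list(boot = boot, test = test)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      boot_mat[b, ] <- res$boot
      test_mat[b, ] <- res$test
    }
  })
  if (n_failed == B)
    stop("all bootstrap replicates failed to fit", call. = FALSE)
  if (n_failed / B > 0.05)
    stop(sprintf("bootstrap failure rate %.1f%% exceeds 5%%",
                 100 * n_failed / B), call. = FALSE)
  ok <- !is.na(boot_mat[, 1])
  optimism <- colMeans(boot_mat[ok, , drop = FALSE] -
                         test_mat[ok, , drop = FALSE])
  names(optimism) <- names(apparent)
  structure(list(
    apparent = apparent, optimism = optimism,
    corrected = apparent - optimism,
    B = B, seed = seed, n_failed = n_failed
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Bootstrap internal validation (B = %d, %d failed replicates)\n",
              x$B, x$n_failed))
  print(round(cbind(apparent = x$apparent, optimism = x$optimism,
                    corrected = x$corrected), 4))
  invisible(x)
}
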