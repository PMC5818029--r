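# Firth penalised-likelihood logistic regression.
#
# The penalised log-likelihood is l*(b) = l(b) + 0.5 * log det(X'WX),
# W = diag(pi(1-pi)), whose gradient is the Firth-modified score
#   U*_j(b) = sum_i (y_i - pi_i + h_i (1/2 - pi_i)) x_ij,
# h_i the hat diagonals of the weighted design. The Jeffreys-prior penalty
# keeps estimates finite under complete separation (as for finger-like
# projections, present only in the moderate/severe-CAA group) and reduces
# small-sample bias.

#' Build a logistic design matrix
#'
#' @param data data.frame (typically a `caa_cohort`).
#' @param outcome name of the binary outcome column.
#' @param predictors character vector of predictor column names.
#' @return list with `X` (n x p, first column intercept), `y`, `labels`.
#' @export
design_matrix <- function(data, outcome = "outcome",
                          predictors = c("apoe_e4", "sah", "flp")) {
  data <- as.data.frame(data)
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss))
    stop("columns not in data: ", paste(miss, collapse = ", "), call. = FALSE)
  y <- data[[outcome]]
  if (any(!y %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  if (nrow(X) < ncol(X))
    stop("need at least as many rows as coefficients", call. = FALSE)
  list(X = X, y = as.numeric(y), labels = colnames(X))
}

# Bernoulli log-likelihood, numerically safe via plogis on the log scale
bernoulli_loglik <- function(eta, y) {
  sum(y * stats::plogis(eta, log.p = TRUE) +
        (1 - y) * stats::plogis(-eta, log.p = TRUE))
}

#' Penalised log-likelihood of a logistic model
#'
#' `l(b) + 0.5 * log det(X'WX)` with `W = diag(pi (1 - pi))`. Returns `-Inf`
#' when the weighted information is numerically singular, so line searches
#' reject such points.
#'
#' @param beta coefficient vector of length `ncol(X)`.
#' @param design a list from [design_matrix()] (or any list with `X`, `y`).
#' @return scalar penalised log-likelihood.
#' @export
penalized_loglik <- function(beta, design) {
  X <- design$X; y <- design$y
  stopifnot(length(beta) == ncol(X))
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pi * (1 - pi)
  info <- crossprod(X * sqrt(w))
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) return(-Inf)
  bernoulli_loglik(eta, y) + 0.5 * as.numeric(ld$modulus)
}

# modified score and ingredients at beta; shared by fitter and profiler
firth_ingredients <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- pi * (1 - pi)
  Xw <- X * sqrt(w)
  info <- crossprod(Xw)
  inv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  h <- rowSums((Xw %*% inv) * Xw)
  score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
  list(eta = eta, pi = pi, w = w, info = info, inv = inv, h = h,
       score = score)
}

#' Fit a Firth penalised-likelihood logistic regression
#'
#' Newton-Raphson on the modified score, with step-halving whenever a step
#' would decrease the penalised log-likelihood. Estimates are finite even
#' under complete separation. Standard errors come from the inverse penalised
#' information at the optimum.
#'
#' @param design list from [design_matrix()], or a data.frame (then `outcome`
#'   and `predictors` are used to build the design).
#' @param outcome,predictors used when `design` is a data.frame.
#' @param tol convergence tolerance on both `max|delta beta|` and the maximum
#'   absolute modified score (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50).
#' @param step_halving_max maximum halvings per iteration (default 10).
#' @return a `firth_fit`: coefficients, `se`, penalised and unpenalised
#'   log-likelihoods, fitted probabilities, hat diagonals, iteration count,
#'   convergence flag, and the AIC convention `-2 l(beta) + 2p` (unpenalised
#'   log-likelihood at the Firth estimates).
#' @examples
#' fit <- fit_firth(fixture_cohort())
#' coef(fit)
#' @export
fit_firth <- function(design, outcome = "outcome",
                      predictors = c("apoe_e4", "sah", "flp"),
                      tol = 1e-8, max_iter = 50L, step_halving_max = 10L) {
  if (is.data.frame(design))
    design <- design_matrix(design, outcome, predictors)
  X <- design$X; y <- design$y
  p <- ncol(X); n <- nrow(X)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dep <- design$labels[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  const <- apply(X[, -1, drop = FALSE], 2, function(col) length(unique(col)) == 1L)
  if (any(const))
    stop("constant non-intercept column(s): ",
         paste(colnames(X)[-1][const], collapse = ", "), call. = FALSE)

  beta <- rep(0, p)
  ll <- penalized_loglik(beta, design)
  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    ing <- firth_ingredients(beta, X, y)
    if (is.null(ing))
      stop("penalised information singular at iteration ", iter, call. = FALSE)
    delta <- drop(ing$inv %*% ing$score)
    step <- 1
    for (half in 0:step_halving_max) {
      cand <- beta + step * delta
      ll_cand <- penalized_loglik(cand, design)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-12) break
      step <- step / 2
    }
    ll_prev <- ll
    beta <- cand
    ll <- ll_cand
    trace <- c(trace, ll)
    score_new <- firth_ingredients(beta, X, y)$score
    # converged when the modified score vanishes and either the step is
    # below tolerance or the objective is numerically stationary (flat
    # likelihood regions under near-singular curvature)
    if (max(abs(score_new)) < tol &&
        (max(abs(step * delta)) < tol || abs(ll - ll_prev) < 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "Firth fit did not converge in %d iterations (last max|U*| = %.3g)",
      iter, max(abs(score_new))))
    cond$iteration_trace <- trace
    stop(cond)
  }
  ing <- firth_ingredients(beta, X, y)
  eta <- drop(X %*% beta)
  names(beta) <- design$labels
  se <- sqrt(diag(ing$inv))
  names(se) <- design$labels
  structure(list(
    coefficients = beta, se = se,
    loglik_penalized = ll,
    loglik_unpenalized = bernoulli_loglik(eta, y),
    fitted = ing$pi, hat = ing$h,
    iter = iter, converged = TRUE, loglik_trace = trace,
    aic = -2 * bernoulli_loglik(eta, y) + 2 * p,
    design = design, n = n, p = p
  ), class = "firth_fit")
}

#' @export
coef.firth_fit <- function(object, ...) object$coefficients

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("Firth penalised logistic regression (n = %d, %d iterations)\n",
              x$n, x$iter))
  tab <- cbind(beta = x$coefficients, se = x$se,
               `exp(beta)` = exp(x$coefficients))
  print(round(tab, 4))
  cat(sprintf("penalised log-lik %.4f, unpenalised %.4f, AIC %.2f\n",
              x$loglik_penalized, x$loglik_unpenalized, x$aic))
  invisible(x)
}

#' Predicted probabilities from a Firth fit on new data
#' @param object a `firth_fit`.
#' @param newdata optional data.frame with the predictor columns.
#' @param ... unused.
#' @export
predict.firth_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  preds <- object$design$labels[-1]
  X <- cbind(1, as.matrix(as.data.frame(newdata)[preds]))
  drop(stats::plogis(X %*% object$coefficients))
}

#' Wald tests for Firth coefficients
#'
#' `z = beta / se` against the standard normal; standard errors from the
#' inverse penalised information at the optimum.
#'
#' @param fit a converged `firth_fit`.
#' @return data.frame with `beta`, `se`, `z`, `p`, `odds_ratio` per coefficient.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "firth_fit"), fit$converged)
  z <- fit$coefficients / fit$se
  data.frame(term = names(fit$coefficients),
             beta = unname(fit$coefficients), se = unname(fit$se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             odds_ratio = unname(exp(fit$coefficients)),
             row.names = NULL)
}

# profile penalised log-likelihood: max over the other coefficients with
# coefficient j fixed at b; BFGS started from the unconstrained optimum
profile_value <- function(fit, j, b) {
  design <- fit$design
  p <- fit$p
  if (p == 1L) return(penalized_loglik(b, design))
  full <- function(free) {
    beta <- numeric(p); beta[j] <- b; beta[-j] <- free
    beta
  }
  start <- fit$coefficients[-j]
  opt <- stats::optim(
    start,
    fn = function(free) -penalized_loglik(full(free), design),
    gr = function(free) {
      ing <- firth_ingredients(full(free), design$X, design$y)
      if (is.null(ing)) return(rep(0, p - 1))
      -ing$score[-j]
    },
    method = "BFGS", control = list(maxit = 200, reltol = 1e-12))
  -opt$value
}

#' Profile penalised-likelihood confidence intervals
#'
#' For each coefficient, the bounds solve
#' `2 (l*(beta_hat) - max_{beta: beta_j = b} l*(beta)) = qchisq(level, 1)`
#' by bracketed root-finding. When no root exists before `|b|` reaches
#' `bound_cap` the side is flagged `"not reached"` (the profile is flat, as
#' happens above a completely separated predictor) and the bound is `NA`,
#' never a number.
#'
#' @param fit a converged `firth_fit`.
#' @param level confidence level (default 0.95).
#' @param bound_cap cap on `|b|` (log-odds scale) beyond which a side is
#'   declared not reached (default 15).
#' @return data.frame with `lower`, `upper` (log-odds scale),
#'   `lower_reached`, `upper_reached`.
#' @export
profile_ci <- function(fit, level = 0.95, bound_cap = 15) {
  stopifnot(inherits(fit, "firth_fit"), fit$converged)
  crit <- stats::qchisq(level, 1)
  target <- fit$loglik_penalized - crit / 2
  p <- fit$p
  res <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    lower = NA_real_, upper = NA_real_,
                    lower_reached = FALSE, upper_reached = FALSE,
                    row.names = NULL)
  for (j in seq_len(p)) {
    bhat <- fit$coefficients[j]
    f <- function(b) profile_value(fit, j, b) - target
    for (side in c(-1, 1)) {
      b_in <- bhat
      f_in <- crit / 2  # f(bhat) by construction
      found <- FALSE
      step <- max(0.5, 2 * fit$se[j])
      b_out <- bhat
      repeat {
        b_out <- b_out + side * step
        if (abs(b_out) > bound_cap) break
        f_out <- f(b_out)
        if (!is.finite(f_out)) break
        if (f_out < 0) { found <- TRUE; break }
        b_in <- b_out
      }
      if (found) {
        root <- stats::uniroot(f, sort(c(b_in, b_out)), tol = 1e-7)$root
        if (side < 0) {
          res$lower[j] <- root; res$lower_reached[j] <- TRUE
        } else {
          res$upper[j] <- root; res$upper_reached[j] <- TRUE
        }
      }
    }
  }
  res
}

#' Penalised likelihood-ratio test for nested Firth models
#'
#' `2 (l*_full - l*_reduced)` against chi-square with `df` the difference in
#' number of coefficients. With the reduced model intercept-only this is the
#' overall model chi-square.
#'
#' @param fit_full,fit_reduced converged `firth_fit`s; the reduced model's
#'   columns must be a subset of the full model's.
#' @return list with `statistic`, `df`, `p`.
#' @export
plr_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "firth_fit"), inherits(fit_reduced, "firth_fit"))
  if (!all(fit_reduced$design$labels %in% fit_full$design$labels))
    stop("models are not nested: reduced columns must be a subset of the full model",
         call. = FALSE)
  df <- fit_full$p - fit_reduced$p
  stat <- max(0, 2 * (fit_full$loglik_penalized - fit_reduced$loglik_penalized))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from a least-squares regression of
#' predictor `j` on the remaining predictors plus intercept. Perfect
#' collinearity yields an infinite VIF, flagged.
#'
#' @param design list from [design_matrix()], or a data.frame plus
#'   `predictors`.
#' @param predictors used when `design` is a data.frame.
#' @return named numeric vector of VIFs (may contain `Inf`).
#' @export
compute_vif <- function(design, predictors = c("apoe_e4", "sah", "flp")) {
  if (is.data.frame(design))
    design <- design_matrix(design, predictors = predictors)
  X <- design$X[, -1, drop = FALSE]
  if (ncol(X) < 2L)
    stop("VIF needs at least two non-intercept predictors", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    yj <- X[, j]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((yj - mean(yj))^2)
    r2 <- 1 - ss_res / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}
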