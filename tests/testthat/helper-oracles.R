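# Independent oracles used to freeze expected values. These deliberately
# avoid the package's solvers: the grid maximiser only evaluates the
# penalised log-likelihood objective, the c-statistic oracle enumerates
# pairs, the Fisher oracle enumerates the hypergeometric support.

# coarse-to-fine grid search maximiser of a function over a box;
# each round lays a 13-point grid per dimension and re-centres on the argmax
grid_maximize <- function(f, p, lower = -8, upper = 8, rounds = 8L) {
  centers <- rep((lower + upper) / 2, p)
  width <- upper - lower
  pts_per_dim <- 13L
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(p), function(j)
      seq(centers[j] - width / 2, centers[j] + width / 2,
          length.out = pts_per_dim))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, f)
    best <- which.max(vals)
    centers <- grid[best, ]
    width <- 2 * width / (pts_per_dim - 1)  # +/- one grid step
  }
  list(par = unname(centers), value = max(vals))
}

grid_maximize_pll <- function(design, rounds = 8L) {
  grid_maximize(function(b) caadx::penalized_loglik(b, design),
                p = ncol(design$X), rounds = rounds)
}

# profile curve oracle: g(b) = max over remaining coords with coord j fixed
grid_profile_pll <- function(design, j, b, rounds = 8L) {
  p <- ncol(design$X)
  if (p == 1L) return(caadx::penalized_loglik(b, design))
  grid_maximize(function(free) {
    beta <- numeric(p); beta[j] <- b; beta[-j] <- free
    caadx::penalized_loglik(beta, design)
  }, p = p - 1L, rounds = rounds)$value
}

# exhaustive case-control pair enumeration
c_statistic_oracle <- function(probs, outcomes) {
  cases <- probs[outcomes == 1]
  controls <- probs[outcomes == 0]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

# two-sided Fisher p by full enumeration over the hypergeometric support
fisher_oracle <- function(tab) {
  m <- matrix(tab, 2, 2, byrow = TRUE)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Haldane-Anscombe cross-product odds ratio for a 2x2 of outcome-group rows
# (row 1: y=0 feature+/-, row 2: y=1 feature+/-)
haldane_or <- function(a, b, cc, d) {
  ((cc + 0.5) / (d + 0.5)) / ((a + 0.5) / (b + 0.5))
}

# expand a 2x2 outcome-by-feature table into individual records
expand_2x2 <- function(a, b, cc, d) {
  data.frame(
    outcome = c(rep(0, a + b), rep(1, cc + d)),
    x = c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d)))
}

# deterministic toy designs (p <= 3, n <= 12) for solver/oracle equivalence
toy_designs <- function() {
  list(
    list(x = cbind(x1 = c(0, 0, 1, 1, 0, 1)),
         y = c(0, 1, 0, 1, 0, 1)),
    list(x = cbind(x1 = c(0, 1, 0, 1, 1, 1, 0, 0)),
         y = c(0, 0, 1, 1, 1, 0, 0, 1)),
    list(x = cbind(x1 = c(0, 0, 0, 0, 1, 1, 1, 1),
                   x2 = c(0, 1, 0, 1, 0, 1, 0, 1)),
         y = c(0, 0, 1, 0, 1, 1, 0, 1)),
    list(x = cbind(x1 = c(0, 1, 1, 0, 1, 0, 0, 1, 1, 0),
                   x2 = c(1, 1, 0, 0, 1, 1, 0, 0, 1, 0)),
         y = c(0, 1, 1, 0, 1, 0, 1, 1, 0, 0)),
    list(x = cbind(x1 = c(0, 0, 0, 1, 1, 1, 0, 1, 0, 1, 1, 0),
                   x2 = c(0, 1, 1, 0, 0, 1, 1, 0, 0, 1, 0, 1)),
         y = c(0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 0, 0)))
}

toy_design_matrix <- function(td) {
  df <- as.data.frame(td$x)
  df$outcome <- td$y
  caadx::design_matrix(df, predictors = colnames(td$x))
}
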