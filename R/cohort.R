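# Cohort data model, CAA burden grading, fixture cohort, simulator, CSV I/O.

#' Grade a summed parenchymal CAA score into a burden category
#'
#' Parenchymal CAA scores from the left cerebral hemisphere are summed to a
#' 0-12 burden sum and graded: 0 = none, 1-4 = mild, 5-8 = moderate,
#' 9-12 = severe. A burden of moderate or severe defines the positive outcome
#' (CAA-associated lobar intracerebral haemorrhage).
#'
#' @param sum integer vector of burden sums, each in 0-12.
#' @return character vector with values in `c("none","mild","moderate","severe")`.
#' @examples
#' grade_caa_burden(c(0, 3, 5, 12))
#' @export
grade_caa_burden <- function(sum) {
  if (length(sum) == 0L) return(character(0))
  if (any(is.na(sum)) || any(sum != floor(sum)) || any(sum < 0) || any(sum > 12))
    stop("CAA burden sum must be an integer in 0-12", call. = FALSE)
  c("none", rep("mild", 4), rep("moderate", 4), rep("severe", 4))[sum + 1L]
}

#' Burden categories that define the positive outcome
#' @keywords internal
.positive_categories <- c("moderate", "severe")

# required columns of a cohort; the three model predictors and the outcome
# must be complete ("No data were missing" is an invariant of the design)
.required_cols <- c("id", "outcome", "apoe_e4", "sah", "flp")
.binary_cols   <- c("outcome", "apoe_e4", "apoe_e2", "sah", "flp",
                    "anticoagulant_use", "strictly_lobar")

#' Construct and validate a cohort table
#'
#' A `caa_cohort` is a `data.frame` of participant records with a binary
#' outcome (1 = moderate/severe CAA) and the three binary model predictors:
#' APOE e4 possession (`apoe_e4`), any subarachnoid extension (`sah`) and
#' finger-like projections (`flp`). Optional covariate columns (age, sex,
#' haematoma volume, anticoagulant use, APOE e2, burden sums, ...) are kept
#' as-is.
#'
#' @param data data.frame with at least `id`, `outcome` (or `caa_burden_sum`),
#'   `apoe_e4`, `sah`, `flp`.
#' @param provenance one of `"fixture"`, `"simulated"`, `"user"`.
#' @param seed optional integer seed recorded for simulated cohorts.
#' @return a `caa_cohort` (also a `data.frame`).
#' @export
caa_cohort <- function(data, provenance = c("user", "fixture", "simulated"),
                       seed = NULL) {
  provenance <- match.arg(provenance)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"outcome" %in% names(data) && "caa_burden_sum" %in% names(data)) {
    data$caa_burden_category <- grade_caa_burden(data$caa_burden_sum)
    data$outcome <- as.integer(data$caa_burden_category %in% .positive_categories)
  }
  missing_cols <- setdiff(.required_cols, names(data))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id))
    stop("participant ids must be unique", call. = FALSE)
  for (col in intersect(.binary_cols, names(data))) {
    data[[col]] <- normalise_binary(data[[col]], col)
  }
  core <- c("outcome", "apoe_e4", "sah", "flp")
  if (anyNA(data[core]))
    stop("outcome and model predictors must have no missing values",
         call. = FALSE)
  if ("caa_burden_sum" %in% names(data)) {
    ok <- is.na(data$caa_burden_sum)
    cat_from_sum <- grade_caa_burden(data$caa_burden_sum[!ok])
    if ("caa_burden_category" %in% names(data) &&
        any(cat_from_sum != data$caa_burden_category[!ok], na.rm = TRUE))
      stop("caa_burden_sum inconsistent with caa_burden_category", call. = FALSE)
    implied <- as.integer(cat_from_sum %in% .positive_categories)
    if (any(implied != data$outcome[!ok]))
      stop("outcome inconsistent with caa_burden_sum grading", call. = FALSE)
  }
  rownames(data) <- NULL
  structure(data,
            provenance = provenance, seed = seed,
            class = c("caa_cohort", "data.frame"))
}

# accepts 0/1, TRUE/FALSE, "true"/"false", "yes"/"no" (any case)
normalise_binary <- function(x, name) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (any(!x %in% c(0, 1, NA)))
      stop(sprintf("column '%s' must be binary (0/1)", name), call. = FALSE)
    return(as.integer(x))
  }
  lx <- tolower(trimws(as.character(x)))
  map <- c("0" = 0L, "1" = 1L, "false" = 0L, "true" = 1L,
           "no" = 0L, "yes" = 1L)
  out <- unname(map[lx])
  bad <- which(is.na(out) & !is.na(lx) & nzchar(lx))
  if (length(bad))
    stop(sprintf("column '%s': unparseable binary value '%s' in row %d",
                 name, x[bad[1]], bad[1]), call. = FALSE)
  out
}

#' @export
print.caa_cohort <- function(x, ...) {
  cat(sprintf("<caa_cohort> %d participants (%d with moderate/severe CAA), provenance: %s\n",
              nrow(x), sum(x$outcome), attr(x, "provenance")))
  NextMethod()
}

#' Synthetic fixture cohort of 62 lobar intracerebral haemorrhages
#'
#' A deterministic reconstruction of the Edinburgh derivation cohort: 62
#' participants with lobar intracerebral haemorrhage, 36 with moderate or
#' severe CAA and 26 with absent or mild CAA. The marginal counts of the
#' three predictors match the published group counts exactly (SAH 11/26 and
#' 32/36; APOE e4 2/26 and 18/36; finger-like projections 0/26 and 14/36).
#'
#' The individual-level joint distribution is not published, so the joint
#' predictor cells are pinned by the published accuracy statistics:
#' \itemize{
#'   \item all 4 CAA-positive cases without SAH carry APOE e4 (forced by the
#'     100\% sensitivity of the rule-out criteria);
#'   \item exactly 1 CAA-negative case has both SAH and e4 (forced by the
#'     96\% = 25/26 specificity of the rule-in criteria);
#'   \item 9 of the 14 finger-like-projection cases sit in SAH-positive,
#'     e4-negative cells (forced by the positive likelihood ratio 16.6,
#'     i.e. 23/36 rule-in positives among cases);
#'   \item the residual split of projections across e4 strata (9 vs 5) is an
#'     assumption — it is not identified by any published statistic.
#' }
#' Covariate columns (age, sex, volume, APOE e2, anticoagulant use, strictly
#' lobar location, burden sums) are deterministic synthetic fillers whose
#' group counts match the published summary table where one is printed; they
#' are not individual-level data.
#'
#' @return a `caa_cohort` with provenance `"fixture"`.
#' @examples
#' fix <- fixture_cohort()
#' table(fix$outcome, fix$sah)
#' @export
fixture_cohort <- function() {
  # pattern blocks: (sah, e4, flp) x count, per outcome group
  g0 <- rbind(
    matrix(rep(c(0, 0, 0), 14), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE),
    c(0, 1, 0),
    c(1, 1, 0))
  g1 <- rbind(
    matrix(rep(c(1, 0, 0), 9), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 0, 1), 9), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 1, 0), 9), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 1, 1), 5), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 1, 0), 4), ncol = 3, byrow = TRUE))
  pat <- rbind(g0, g1)
  n0 <- nrow(g0); n1 <- nrow(g1); n <- n0 + n1
  outcome <- c(rep(0L, n0), rep(1L, n1))

  anticoag <- integer(n); anticoag[c(1, 2, 15, 16, 27, 28, 36, 37, 45)] <- 1L
  e2 <- integer(n); e2[c(3, 4, 17, 29, 30, 38, 39, 46, 47, 48, 51, 52, 59, 60)] <- 1L
  strictly_lobar <- rep(1L, n); strictly_lobar[c(5, 6, 7, 18)] <- 0L
  burden <- c(rep(0:4, length.out = n0), rep(5:12, length.out = n1))
  sex <- c(rep("M", 12), rep("F", 14), rep("M", 11), rep("F", 25))
  age <- as.integer(c(round(seq(78, 88, length.out = n0)),
                      round(seq(79, 85, length.out = n1))))
  vol <- as.integer(c(round(seq(23, 126, length.out = n0)),
                      round(seq(22, 117, length.out = n1))))

  caa_cohort(data.frame(
    id = sprintf("P%03d", seq_len(n)),
    outcome = outcome,
    caa_burden_sum = burden,
    caa_burden_category = grade_caa_burden(burden),
    apoe_e4 = as.integer(pat[, 2]),
    apoe_e2 = e2,
    sah = as.integer(pat[, 1]),
    flp = as.integer(pat[, 3]),
    ich_location = "lobar",
    strictly_lobar = strictly_lobar,
    age_years = age,
    sex = sex,
    ich_volume_ml = vol,
    anticoagulant_use = anticoag,
    stringsAsFactors = FALSE
  ), provenance = "fixture")
}

#' Canonical predictor patterns
#'
#' The 8 combinations of (apoe_e4, sah, flp), ordered by binary counting with
#' `apoe_e4` most significant.
#' @return data.frame with columns `apoe_e4`, `sah`, `flp`.
#' @export
predictor_patterns <- function() {
  g <- expand.grid(flp = 0:1, sah = 0:1, apoe_e4 = 0:1)
  data.frame(apoe_e4 = g$apoe_e4, sah = g$sah, flp = g$flp)
}

#' Simulation configuration
#'
#' Two data-generating modes:
#' \describe{
#'   \item{conditional}{draw predictor patterns within each outcome group from
#'     per-group probability vectors over the 8 patterns of
#'     [predictor_patterns()]; group sizes are fixed (`n_per_group`).}
#'   \item{logistic}{draw `n` predictor patterns from `pattern_probs`, then
#'     draw the outcome Bernoulli with probability
#'     `plogis(b0 + b_e4*e4 + b_sah*sah + b_flp*flp)`.}
#' }
#'
#' @param mode `"conditional"` or `"logistic"`.
#' @param n_per_group length-2 vector `c(n0, n1)` (conditional mode).
#' @param pattern_probs_0,pattern_probs_1 length-8 probability vectors per
#'   outcome group (conditional mode).
#' @param n total sample size (logistic mode).
#' @param pattern_probs length-8 probability vector over patterns (logistic).
#' @param beta length-4 coefficient vector `(b0, b_e4, b_sah, b_flp)` on the
#'   log-odds scale (logistic mode).
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(mode = c("conditional", "logistic"),
                              n_per_group = NULL,
                              pattern_probs_0 = NULL, pattern_probs_1 = NULL,
                              n = NULL, pattern_probs = NULL, beta = NULL,
                              seed = 1L) {
  mode <- match.arg(mode)
  check_probs <- function(p, what) {
    if (length(p) != 8L || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop(sprintf("%s must be 8 non-negative probabilities summing to 1", what),
           call. = FALSE)
    p
  }
  if (mode == "conditional") {
    if (is.null(n_per_group) || length(n_per_group) != 2L || any(n_per_group < 1))
      stop("conditional mode needs n_per_group = c(n0, n1), each >= 1",
           call. = FALSE)
    check_probs(pattern_probs_0, "pattern_probs_0")
    check_probs(pattern_probs_1, "pattern_probs_1")
  } else {
    if (is.null(n) || n < 1) stop("logistic mode needs n >= 1", call. = FALSE)
    check_probs(pattern_probs, "pattern_probs")
    if (is.null(beta) || length(beta) != 4L || any(!is.finite(beta)))
      stop("logistic mode needs a finite length-4 beta", call. = FALSE)
  }
  structure(list(mode = mode, n_per_group = n_per_group,
                 pattern_probs_0 = pattern_probs_0,
                 pattern_probs_1 = pattern_probs_1,
                 n = n, pattern_probs = pattern_probs, beta = beta,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a cohort
#'
#' Reproducible given `config$seed`; see [simulation_config()] for the two
#' data-generating modes.
#'
#' @param config a [simulation_config()].
#' @return a `caa_cohort` with provenance `"simulated"` and the seed recorded.
#' @examples
#' cfg <- simulation_config("logistic", n = 100,
#'                          pattern_probs = rep(1/8, 8),
#'                          beta = c(-2.55, 3.11, 2.31, 3.20), seed = 42)
#' sim <- simulate_cohort(cfg)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  pats <- predictor_patterns()
  df <- with_seed(config$seed, {
    if (config$mode == "conditional") {
      idx0 <- sample.int(8L, config$n_per_group[1], replace = TRUE,
                         prob = config$pattern_probs_0)
      idx1 <- sample.int(8L, config$n_per_group[2], replace = TRUE,
                         prob = config$pattern_probs_1)
      data.frame(outcome = rep(0:1, config$n_per_group),
                 pats[c(idx0, idx1), ], row.names = NULL)
    } else {
      idx <- sample.int(8L, config$n, replace = TRUE,
                        prob = config$pattern_probs)
      x <- pats[idx, ]
      eta <- config$beta[1] + config$beta[2] * x$apoe_e4 +
        config$beta[3] * x$sah + config$beta[4] * x$flp
      data.frame(outcome = stats::rbinom(config$n, 1L, stats::plogis(eta)),
                 x, row.names = NULL)
    }
  })
  df <- cbind(id = sprintf("S%05d", seq_len(nrow(df))), df)
  caa_cohort(df, provenance = "simulated", seed = config$seed)
}

#' Read a cohort from CSV
#'
#' Comma-separated, UTF-8, header required, "." decimal separator. Binary
#' columns accept 0/1, true/false, yes/no. If the file carries
#' `caa_burden_sum` but no `outcome`, the outcome is derived via
#' [grade_caa_burden()] (moderate/severe = 1).
#'
#' @param path file path.
#' @param col_map optional named character vector mapping canonical column
#'   names to names used in the file, e.g. `c(sah = "subarachnoid")`.
#' @return a `caa_cohort` with provenance `"user"`.
#' @export
read_cohort_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("cannot parse CSV: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("empty cohort file: ", path, call. = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df))
        stop("mapped column not found in file: ", col_map[[canon]],
             call. = FALSE)
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  caa_cohort(df, provenance = "user")
}

#' Write a cohort to CSV
#'
#' Round-trips: `read_cohort_csv(write_cohort_csv(x, path))` reproduces every
#' stored field. Optional columns absent from the cohort are simply not
#' written.
#'
#' @param cohort a `caa_cohort`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "caa_cohort"))
  ok <- tryCatch({
    utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write cohort CSV: ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Exclude participants matching a predicate
#'
#' The predicate is an unquoted expression over cohort columns; matching rows
#' are removed (e.g. the sensitivity analysis excluding participants on oral
#' anticoagulants). Row order of the remainder is preserved and the number of
#' removed records is recorded in attribute `"n_removed"`.
#'
#' @param cohort a `caa_cohort`.
#' @param predicate expression selecting rows to exclude,
#'   e.g. `anticoagulant_use == 1`.
#' @return filtered `caa_cohort`.
#' @examples
#' fix <- fixture_cohort()
#' nrow(filter_cohort(fix, anticoagulant_use == 1))  # 53
#' @export
filter_cohort <- function(cohort, predicate) {
  stopifnot(inherits(cohort, "caa_cohort"))
  expr <- substitute(predicate)
  vars <- all.vars(expr)
  unknown <- setdiff(vars, names(cohort))
  if (length(unknown))
    stop("predicate references unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  drop <- eval(expr, envir = as.data.frame(cohort), enclos = parent.frame())
  drop <- isTRUE_vec(drop, nrow(cohort))
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out <- caa_cohort(as.data.frame(out), provenance = attr(cohort, "provenance"),
                    seed = attr(cohort, "seed"))
  attr(out, "n_removed") <- sum(drop)
  out
}

isTRUE_vec <- function(x, n) {
  if (!is.logical(x) || length(x) != n)
    stop("predicate must evaluate to a logical vector over the cohort rows",
         call. = FALSE)
  x & !is.na(x)
}
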