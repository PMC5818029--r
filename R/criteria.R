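# Risk score, predicted probability, risk categorisation, rule-in/rule-out
# diagnostic criteria, and decision curve analysis.

#' Published model coefficients
#'
#' The risk-score equation of the three-predictor diagnostic model on the
#' log-odds scale: intercept -2.55, APOE e4 3.11, subarachnoid haemorrhage
#' 2.31, finger-like projections 3.20.
#'
#' @return named numeric vector `(intercept, apoe_e4, sah, flp)`.
#' @export
default_coefficients <- function() {
  c(intercept = -2.55, apoe_e4 = 3.11, sah = 2.31, flp = 3.20)
}

# normalise pattern input to a data.frame with apoe_e4/sah/flp columns;
# a bare numeric triple is taken in that order
as_pattern_df <- function(pattern) {
  if (is.data.frame(pattern)) {
    miss <- setdiff(c("apoe_e4", "sah", "flp"), names(pattern))
    if (length(miss))
      stop("pattern is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    df <- pattern[c("apoe_e4", "sah", "flp")]
  } else if (is.numeric(pattern) && length(pattern) == 3L) {
    df <- data.frame(apoe_e4 = pattern[1], sah = pattern[2], flp = pattern[3])
  } else {
    stop("pattern must be a binary triple (e4, sah, flp) or a data.frame",
         call. = FALSE)
  }
  if (any(!unlist(df) %in% c(0, 1)))
    stop("pattern values must be 0/1", call. = FALSE)
  df
}

#' Linear risk score of a predictor pattern
#'
#' `intercept + b_e4*e4 + b_sah*sah + b_flp*flp` on the log-odds scale.
#'
#' @param pattern binary triple `c(e4, sah, flp)` or data.frame with columns
#'   `apoe_e4`, `sah`, `flp` (vectorised).
#' @param coefficients named coefficient vector; default the published model.
#' @return numeric risk score(s).
#' @examples
#' risk_score(c(0, 0, 0))  # -2.55
#' @export
risk_score <- function(pattern, coefficients = default_coefficients()) {
  df <- as_pattern_df(pattern)
  unname(coefficients[["intercept"]] +
           coefficients[["apoe_e4"]] * df$apoe_e4 +
           coefficients[["sah"]] * df$sah +
           coefficients[["flp"]] * df$flp)
}

#' Predicted probability of moderate/severe CAA for a pattern
#'
#' Logistic transform of [risk_score()].
#' @inheritParams risk_score
#' @export
predicted_probability <- function(pattern, coefficients = default_coefficients()) {
  stats::plogis(risk_score(pattern, coefficients))
}

#' Risk category of a predictor pattern
#'
#' Categories are defined by the predictor combinations, not by numeric
#' probability thresholds: low when neither SAH nor APOE e4 is present; high
#' when SAH is present together with at least one other predictor; medium
#' otherwise. With the published coefficients these correspond to predicted
#' probabilities of at most 7\%, 44-64\%, and 95\% or more.
#'
#' @inheritParams risk_score
#' @return character vector in `c("low", "medium", "high")`.
#' @export
classify_risk <- function(pattern) {
  df <- as_pattern_df(pattern)
  ifelse(df$sah == 0 & df$apoe_e4 == 0, "low",
         ifelse(df$sah == 1 & (df$apoe_e4 == 1 | df$flp == 1), "high",
                "medium"))
}

#' Rule-out criteria: is CAA ruled out?
#'
#' CAA-associated haemorrhage is ruled out when neither subarachnoid
#' haemorrhage nor APOE e4 possession is present (the low-risk group;
#' 100\% sensitive in the derivation cohort).
#' @inheritParams risk_score
#' @return logical vector.
#' @export
apply_rule_out <- function(pattern) {
  df <- as_pattern_df(pattern)
  df$sah == 0 & df$apoe_e4 == 0
}

#' Rule-in criteria: is CAA ruled in?
#'
#' CAA-associated haemorrhage is ruled in by subarachnoid haemorrhage together
#' with APOE e4 possession or finger-like projections (the high-risk group;
#' 96\% specific in the derivation cohort).
#' @inheritParams risk_score
#' @return logical vector.
#' @export
apply_rule_in <- function(pattern) {
  df <- as_pattern_df(pattern)
  df$sah == 1 & (df$apoe_e4 == 1 | df$flp == 1)
}

#' Enumerate the 8 predictor-pattern risk profiles
#'
#' @param coefficients coefficient vector (default the published model).
#' @return data.frame with one row per pattern: predictors, risk score,
#'   predicted probability, risk category, rule-in and rule-out flags.
#' @examples
#' enumerate_profiles()
#' @export
enumerate_profiles <- function(coefficients = default_coefficients()) {
  pats <- predictor_patterns()
  data.frame(
    pats,
    risk_score = risk_score(pats, coefficients),
    probability = predicted_probability(pats, coefficients),
    category = classify_risk(pats),
    rule_out_negative = apply_rule_out(pats),
    rule_in_positive = apply_rule_in(pats)
  )
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at threshold probability `p_t`,
#' classifying positive when `prob >= p_t`:
#' `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)`,
#' with treat-all and treat-none reference strategies.
#'
#' @param probs predicted probabilities.
#' @param outcomes binary outcomes.
#' @param thresholds threshold grid in (0, 1); default 0.01-0.99 step 0.01.
#' @return a `decision_curve` data.frame with columns `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`; prevalence in attribute `"prevalence"`.
#' @export
decision_curve <- function(probs, outcomes,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  n <- length(outcomes)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(length(probs) == n, all(thresholds > 0 & thresholds < 1))
  prev <- mean(outcomes)
  odds <- thresholds / (1 - thresholds)
  nb_model <- vapply(seq_along(thresholds), function(i) {
    pos <- probs >= thresholds[i]
    sum(pos & outcomes == 1) / n - sum(pos & outcomes == 0) / n * odds[i]
  }, numeric(1))
  nb_all <- prev - (1 - prev) * odds
  out <- data.frame(threshold = thresholds, nb_model = nb_model,
                    nb_all = nb_all, nb_none = 0)
  attr(out, "prevalence") <- prev
  class(out) <- c("decision_curve", "data.frame")
  out
}
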