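# Regression and virtual-screening metrics.

#' Mean squared error
#'
#' @param pred,target Equal-length non-empty numeric vectors.
#' @return Scalar MSE.
#' @export
mse <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) == 0) {
    rlang::abort("pred and target must be non-empty and equal length.",
                 class = "cpinet_contract_error")
  }
  mean((pred - target)^2)
}

#' Concordance index
#'
#' Over all pairs with distinct target values, the fraction predicted in the
#' same order as the targets; tied predictions earn half credit.
#'
#' @param pred,target Numeric vectors (>= 2 observations, not all targets
#'   equal).
#' @return Value in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 3, 2, 4), c(1, 2, 3, 4))  # 5/6
#' @export
concordance_index <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 2) {
    rlang::abort("Need >= 2 paired observations.",
                 class = "cpinet_contract_error")
  }
  n <- length(target)
  credit <- 0; pairs <- 0
  for (i in seq_len(n - 1)) {
    dt <- target[(i + 1):n] - target[i]
    dp <- pred[(i + 1):n] - pred[i]
    use <- dt != 0
    pairs <- pairs + sum(use)
    credit <- credit + sum((sign(dp[use]) == sign(dt[use])) * 1 +
                             (dp[use] == 0) * 0.5)
  }
  if (pairs == 0) {
    rlang::abort("Concordance undefined: all target values are equal.",
                 class = "cpinet_contract_error")
  }
  credit / pairs
}

.check_screen <- function(scores, is_active) {
  if (length(scores) != length(is_active)) {
    rlang::abort("scores and is_active must have equal length.",
                 class = "cpinet_contract_error")
  }
  n_act <- sum(is_active != 0)
  if (n_act == 0 || n_act == length(scores)) {
    rlang::abort("Enrichment metrics need both actives and inactives.",
                 class = "cpinet_contract_error")
  }
  n_act
}

# descending-score ranks with stable order for ties (documented; a seeded
# random tie-break is available)
.screen_ranks <- function(scores, tie_break = c("stable", "random"),
                          seed = NULL) {
  tie_break <- match.arg(tie_break)
  if (anyDuplicated(scores) && tie_break == "stable") {
    rlang::warn("Tied scores broken by stable input order.",
                .frequency = "once", .frequency_id = "cpinet_ties")
  }
  if (tie_break == "random") {
    if (!is.null(seed)) set.seed(seed)
    ord <- order(-scores, sample(length(scores)))
  } else {
    ord <- order(-scores)  # stable in R
  }
  order(ord)   # rank of each item, 1 = best
}

#' Enrichment factor
#'
#' Standard definition (default): the fraction of actives recovered in the top
#' `fraction` of the score-ranked screen divided by `fraction`. The
#' decoy-referenced variant instead reads off the fraction of actives
#' retrieved at the score threshold where `fraction` of the decoys have been
#' retrieved, divided by `fraction`.
#'
#' @param scores Predicted scores (higher = more likely active).
#' @param is_active Binary activity labels.
#' @param fraction Screening fraction in `(0, 1]` (e.g. 0.01 for EF1%).
#' @param definition `"standard"` or `"decoy_referenced"`.
#' @param tie_break `"stable"` (default, warned once) or `"random"`.
#' @param seed Seed for random tie-breaking.
#' @return Enrichment factor (1 = random expectation for the standard
#'   definition).
#' @export
enrichment_factor <- function(scores, is_active, fraction = 0.01,
                              definition = c("standard", "decoy_referenced"),
                              tie_break = c("stable", "random"), seed = NULL) {
  definition <- match.arg(definition)
  n_act <- .check_screen(scores, is_active)
  if (fraction <= 0 || fraction > 1) {
    rlang::abort("fraction must be in (0, 1].", class = "cpinet_contract_error")
  }
  N <- length(scores)
  ranks <- .screen_ranks(scores, tie_break, seed)
  act <- is_active != 0
  if (definition == "standard") {
    top <- ceiling(fraction * N)
    hits <- sum(act & ranks <= top)
    (hits / n_act) / fraction
  } else {
    n_dec <- N - n_act
    dec_ranks <- sort(ranks[!act])
    k <- max(1L, ceiling(fraction * n_dec))
    cutoff <- dec_ranks[k]
    hits <- sum(act & ranks < cutoff)
    (hits / n_act) / fraction
  }
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of the ROC (Truchon & Bailey):
#' exponentially down-weights late ranks so early enrichment dominates.
#' `alpha = 80.5` emphasises roughly the top 2% of the screen.
#'
#' @inheritParams enrichment_factor
#' @param alpha Early-recognition weight (> 0).
#' @return Value in `[0, 1]`.
#' @export
bedroc <- function(scores, is_active, alpha = 80.5,
                   tie_break = c("stable", "random"), seed = NULL) {
  if (alpha <= 0) {
    rlang::abort("alpha must be positive.", class = "cpinet_contract_error")
  }
  n_act <- .check_screen(scores, is_active)
  N <- length(scores)
  ranks <- .screen_ranks(scores, tie_break, seed)
  r_i <- ranks[is_active != 0]
  ra <- n_act / N
  rie <- sum(exp(-alpha * r_i / N)) /
    (ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  val <- rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
  min(max(val, 0), 1)  # guard float underflow at the bounds
}

#' Evaluate predictions against labels
#'
#' Regression mode reports MSE and concordance index; screening mode
#' additionally reports the enrichment factor and BEDROC for a binary
#' activity column.
#'
#' @param data Data frame with a prediction column and a label column.
#' @param pred,truth Column names (default `.pred`, `affinity`).
#' @param activity Optional binary activity column name enabling screening
#'   metrics.
#' @param ef_fraction Enrichment fraction (default 0.01).
#' @param alpha BEDROC alpha (default 80.5).
#' @param ef_definition Passed to [enrichment_factor()].
#' @return One-row tibble of metrics.
#' @export
evaluate_predictions <- function(data, pred = ".pred", truth = "affinity",
                                 activity = NULL, ef_fraction = 0.01,
                                 alpha = 80.5,
                                 ef_definition = c("standard",
                                                   "decoy_referenced")) {
  ef_definition <- match.arg(ef_definition)
  p <- data[[pred]]; y <- data[[truth]]
  if (is.null(p) || is.null(y)) {
    rlang::abort("Prediction/label columns not found.",
                 class = "cpinet_data_error")
  }
  out <- tibble::tibble(n = length(p), mse = mse(p, y),
                        ci = concordance_index(p, y))
  if (!is.null(activity)) {
    act <- data[[activity]]
    out[[paste0("ef", ef_fraction * 100)]] <-
      enrichment_factor(p, act, ef_fraction, definition = ef_definition)
    out[[paste0("bedroc", alpha)]] <- bedroc(p, act, alpha)
  }
  out
}
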