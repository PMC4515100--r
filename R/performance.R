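# Performance measures and the two evaluation strategies.
#
# "Pooled performance": compute the measure within each imputation replicate
# and combine the M estimates by Rubin's rules. "Pooled prediction": average
# the predictions first and compute a single measure on the pooled values.

#' Mean squared prediction error
#'
#' `mean((y - pred)^2)`; for binary outcomes with predicted probabilities
#' this is the Brier score. The sampling variance is the sample variance of
#' the squared errors divided by `n`.
#'
#' @param y Outcome vector (0/1 for binary outcomes).
#' @param pred Response-scale predictions.
#' @return List with `estimate` and `variance`.
#' @export
mspe <- function(y, pred) {
  if (!length(y)) stop("empty input")
  if (length(y) != length(pred)) stop("y and pred differ in length")
  sq <- (y - pred)^2
  list(estimate = mean(sq),
       variance = if (length(sq) > 1L) stats::var(sq) / length(sq) else 0)
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance via midranks: `(concordant + 0.5 * tied pairs) /
#' (n1 * n0)`, with the Hanley-McNeil variance.
#'
#' @param y Binary outcome vector (both classes must be present).
#' @param score Prediction scores (any scale monotone in risk).
#' @return List with `estimate` and `variance`.
#' @export
auroc <- function(y, score) {
  if (length(y) != length(score)) stop("y and score differ in length")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("degenerate outcome: both classes required")
  r <- rank(score)
  A <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) /
    (n1 * n0)
  list(estimate = A, variance = max(v, 0))
}

#' Calibration slope
#'
#' Regresses observed outcomes on predictions: a least-squares regression of
#' `y` on the response-scale predictions for the identity link, or a
#' logistic regression of `y` on the linear predictor for the logit link. A
#' correct set of predictions -- in particular, predictions evaluated on the
#' same data used to estimate them -- gives a slope of 1.
#'
#' @param y Outcome vector.
#' @param pred Response-scale predictions (identity link) or linear
#'   predictors (logit link).
#' @param link `"identity"` or `"logit"`.
#' @return List with `estimate` (slope) and `se`.
#' @export
calibration_slope <- function(y, pred, link = c("identity", "logit")) {
  link <- match.arg(link)
  if (stats::var(pred) == 0) stop("undefined slope: constant predictions")
  X <- cbind(1, pred)
  if (link == "identity") {
    fit <- fit_glm_matrix(X, y, "identity")
  } else {
    fit <- fit_glm_matrix(X, y, "logit")
  }
  list(estimate = unname(fit$coefficients[2L]),
       se = sqrt(fit$vcov[2L, 2L]))
}

#' @keywords internal
measure_fn <- function(measure, link) {
  switch(measure,
         mspe = function(y, v, lp) mspe(y, v),
         auroc = function(y, v, lp) auroc(y, v),
         calibration_slope = function(y, v, lp) {
           est <- if (link == "identity") calibration_slope(y, v, link)
                  else calibration_slope(y, lp, link)
           list(estimate = est$estimate, variance = est$se^2)
         },
         stop("unknown measure '", measure, "'"))
}

#' @keywords internal
performance_estimate <- function(measure, estimate, W, B, T, M, strategy,
                                 transform = "none") {
  structure(list(measure = measure, estimate = estimate, W = W, B = B,
                 T = T, M = M, strategy = strategy, transform = transform),
            class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s (%s): %.*f (T = %.*g)\n", x$measure, x$strategy,
              digits, x$estimate, digits, x$T))
  invisible(x)
}

#' Pooled-performance strategy
#'
#' Computes the measure and its sampling variance within each replicate
#' column of a replicated prediction set (on the logit scale first if
#' `transform = "logit"`, useful for AUROC), then combines by Rubin's rules:
#' point = mean, `W` = mean sampling variance, `B` = between-replicate
#' variance, `T = W + (1 + 1/M) B`. The point estimate is back-transformed
#' if a transform was used.
#'
#' @param y Full outcome vector (subset to the prediction rows internally).
#' @param preds A replicated `prediction_set` (P1/P4/P7 family).
#' @param measure `"mspe"`, `"auroc"` or `"calibration_slope"`.
#' @param transform `"none"` or `"logit"` (pooling scale).
#' @return A `performance_estimate` with strategy `"pooled_performance"`.
#' @export
pool_performance <- function(y, preds,
                             measure = c("mspe", "auroc",
                                         "calibration_slope"),
                             transform = c("none", "logit")) {
  measure <- match.arg(measure)
  transform <- match.arg(transform)
  yy <- y[preds$rows]
  fn <- measure_fn(measure, preds$link)
  R <- ncol(preds$values)
  ests <- numeric(R)
  vars <- numeric(R)
  for (r in seq_len(R)) {
    m <- tryCatch(fn(yy, preds$values[, r], preds$lp[, r]),
                  error = function(e) {
                    stop("measure '", measure, "' failed on replicate ", r,
                         ": ", conditionMessage(e))
                  })
    if (transform == "logit") {
      g <- m$estimate * (1 - m$estimate)
      ests[r] <- stats::qlogis(m$estimate)
      vars[r] <- m$variance / g^2
    } else {
      ests[r] <- m$estimate
      vars[r] <- m$variance
    }
  }
  W <- mean(vars)
  B <- if (R > 1L) stats::var(ests) else 0
  point <- mean(ests)
  Tv <- W + (1 + 1 / R) * B
  if (transform == "logit") point <- stats::plogis(point)
  performance_estimate(measure, point, W, B, Tv, R,
                       "pooled_performance", transform)
}

#' Pooled-prediction strategy
#'
#' Applies the measure once, directly to a single-replicate (pooled)
#' prediction set. No between-imputation variance component exists under
#' this strategy; `B` is `NA`.
#'
#' @inheritParams pool_performance
#' @param pooled A single-replicate `prediction_set` (P2/P3/P5/P6/P8/P9
#'   family).
#' @return A `performance_estimate` with strategy `"pooled_prediction"`.
#' @export
evaluate_pooled_prediction <- function(y, pooled,
                                       measure = c("mspe", "auroc",
                                                   "calibration_slope")) {
  measure <- match.arg(measure)
  if (ncol(pooled$values) != 1L) {
    stop("pooled prediction set must have exactly one replicate")
  }
  yy <- y[pooled$rows]
  m <- measure_fn(measure, pooled$link)(yy, pooled$values[, 1L],
                                        pooled$lp[, 1L])
  performance_estimate(measure, m$estimate, m$variance, NA_real_,
                       m$variance, 1L, "pooled_prediction")
}
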