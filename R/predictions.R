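# The taxonomy of predictions from a model fitted to multiply imputed data.
#
# Nine constructions arise from crossing three covariate sources (fully
# observed rows; the primary imputations x^(k) used to derive the model; a
# secondary set x^(j) imputed without the outcome) with three treatments of
# the imputation replicates (keep them; average on the response scale;
# average on the linear-predictor scale):
#
#   source                 replicated   pooled response   pooled linear
#   complete cases             P1            P2               P3
#   primary imputations        P4            P5               P6
#   secondary imputations      P7            P8               P9
#
# Either the imputation-specific coefficient vectors or the Rubin-pooled
# vector can be used throughout.

#' @keywords internal
link_fn <- function(link) if (link == "identity") identity else expit

#' @keywords internal
prediction_set <- function(lp, label, coef_mode, rows, link,
                           replicate_index = NULL, values = NULL) {
  lp <- as.matrix(lp)
  if (is.null(values)) values <- link_fn(link)(lp)
  structure(
    list(values = as.matrix(values), lp = lp, label = label,
         coef_mode = coef_mode, rows = rows, link = link,
         replicate_index = replicate_index),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("prediction_set", x$label, "|", ncol(x$values), "replicate(s) x",
      nrow(x$values), "individuals |", x$coef_mode, "coefficients\n")
  invisible(x)
}

#' Rows whose model covariates are all observed
#' @param mdata A `missing_data` object.
#' @param covariates Covariate names defining completeness (default: the
#'   model covariates present in the data).
#' @return Integer row indices.
#' @export
complete_rows <- function(mdata, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(model_covariates(mdata$specs),
                            names(mdata$data))
  }
  which(rowSums(mdata$mask[, covariates, drop = FALSE]) == 0L)
}

#' Construct replicated predictions (P1, P4, P7)
#'
#' Builds response-scale predictions with one column per replicate:
#'
#' * `source` a `missing_data` object: P1 -- predictions for the complete
#'   cases only, one column per imputation-specific coefficient vector.
#' * `source` a primary `imputed_stack`: P4 -- dataset `k` is paired with
#'   coefficient vector `k`; covers all rows.
#' * `source` a secondary `imputed_stack` (built excluding the outcome):
#'   P7 -- the full `M2 x M` grid of (dataset `j`, coefficient `k`) pairs
#'   under imputation-specific coefficients, or `M2` columns under pooled
#'   coefficients. A `grid = "paired"` option (requires `M == M2`) pairs
#'   `j` with `k` for sensitivity checks.
#'
#' With `coef_mode = "pooled"` every replicate column uses the pooled
#' coefficient vector instead of its own.
#'
#' @param coefs A `coefficient_set` from [fit_per_imputation()].
#' @param source A `missing_data` object or an `imputed_stack`.
#' @param coef_mode `"imputation_specific"` or `"pooled"`.
#' @param grid `"full"` (default) or `"paired"`, P7 only.
#' @return A `prediction_set` (linear predictors stored alongside the
#'   response-scale values).
#' @export
predict_per_imputation <- function(coefs, source,
                                   coef_mode = c("imputation_specific",
                                                 "pooled"),
                                   grid = c("full", "paired")) {
  coef_mode <- match.arg(coef_mode)
  grid <- match.arg(grid)
  stopifnot(inherits(coefs, "coefficient_set"))
  beta_for <- function(k) {
    if (coef_mode == "pooled") coefs$pooled else coefs$coef[k, ]
  }

  if (inherits(source, "missing_data")) {
    rows <- complete_rows(source, coefs$covariates)
    X <- design_matrix(source$data[rows, , drop = FALSE],
                       coefs$covariates, coefs$specs)
    lp <- vapply(seq_len(coefs$M), function(k) drop(X %*% beta_for(k)),
                 numeric(length(rows)))
    return(prediction_set(lp, "P1", coef_mode, rows, coefs$link,
                          replicate_index = data.frame(k = seq_len(coefs$M))))
  }

  stopifnot(inherits(source, "imputed_stack"))
  if (source$provenance == "primary") {
    if (source$M != coefs$M && coef_mode == "imputation_specific") {
      stop("primary stack size must match the number of coefficient vectors")
    }
    n <- nrow(source$datasets[[1L]])
    lp <- vapply(seq_len(source$M), function(k) {
      X <- design_matrix(source$datasets[[k]], coefs$covariates, coefs$specs)
      drop(X %*% beta_for(k))
    }, numeric(n))
    return(prediction_set(lp, "P4", coef_mode, seq_len(n), coefs$link,
                          replicate_index = data.frame(k = seq_len(source$M))))
  }

  # secondary stack: the (j) and (k) indices are distinct imputations
  if (source$include_outcome) {
    stop("contract violation: P7 requires a secondary stack imputed ",
         "without the outcome")
  }
  n <- nrow(source$datasets[[1L]])
  Xj <- lapply(source$datasets, design_matrix,
               covariates = coefs$covariates, specs = coefs$specs)
  if (coef_mode == "pooled") {
    lp <- vapply(Xj, function(X) drop(X %*% coefs$pooled), numeric(n))
    ridx <- data.frame(j = seq_len(source$M))
  } else if (grid == "paired") {
    if (source$M != coefs$M) stop("paired grid requires M == M2")
    lp <- vapply(seq_len(source$M),
                 function(k) drop(Xj[[k]] %*% coefs$coef[k, ]), numeric(n))
    ridx <- data.frame(j = seq_len(source$M), k = seq_len(source$M))
  } else {
    ridx <- expand.grid(k = seq_len(coefs$M), j = seq_len(source$M))
    ridx <- ridx[, c("j", "k")]
    lp <- mapply(function(j, k) drop(Xj[[j]] %*% coefs$coef[k, ]),
                 ridx$j, ridx$k)
  }
  prediction_set(lp, "P7", coef_mode, seq_len(n), coefs$link,
                 replicate_index = ridx)
}

#' @keywords internal
advance_label <- function(label, scale) {
  map <- if (scale == "response") {
    c(P1 = "P2", P4 = "P5", P7 = "P8")
  } else {
    c(P1 = "P3", P4 = "P6", P7 = "P9")
  }
  out <- map[[label]]
  if (is.null(out)) stop("cannot pool predictions labelled '", label, "'")
  out
}

#' Pool replicated predictions on the response scale
#'
#' Row-wise arithmetic mean of the replicate response-scale predictions
#' (P1 -> P2, P4 -> P5, P7 -> P8). Averaging eliminates the
#' between-imputation variability before any performance measure is
#' computed, which is why measures on these pooled predictions can be
#' optimistic when the outcome informed the imputations.
#'
#' @param preds A replicated `prediction_set`.
#' @return A single-replicate `prediction_set`. The linear-predictor slot of
#'   the result is the inverse link of the pooled response where defined.
#' @export
pool_on_response_scale <- function(preds) {
  if (ncol(preds$values) < 2L) stop("predictions are already pooled")
  v <- rowMeans(preds$values)
  lp <- if (preds$link == "identity") v else stats::qlogis(v)
  prediction_set(matrix(lp, ncol = 1L),
                 advance_label(preds$label, "response"),
                 preds$coef_mode, preds$rows, preds$link,
                 values = matrix(v, ncol = 1L))
}

#' Pool replicated predictions on the linear-predictor scale
#'
#' Row-wise mean of the replicate linear predictors, then the inverse link
#' (P1 -> P3, P4 -> P6, P7 -> P9). For the identity link this coincides with
#' [pool_on_response_scale()]; under the logit link the two differ by a
#' Jensen gap whenever the replicate linear predictors disagree.
#'
#' @param preds A replicated `prediction_set`.
#' @return A single-replicate `prediction_set`.
#' @export
pool_on_linear_scale <- function(preds) {
  if (ncol(preds$lp) < 2L) stop("predictions are already pooled")
  if (anyNA(preds$lp)) {
    stop("linear predictors unavailable (response values at 0/1 cannot be ",
         "inverted)")
  }
  lp <- rowMeans(preds$lp)
  prediction_set(matrix(lp, ncol = 1L),
                 advance_label(preds$label, "linear"),
                 preds$coef_mode, preds$rows, preds$link)
}
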