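# Partial prediction models: one model per observed-covariate pattern, so
# individuals with missing predictors get a prediction from their observed
# covariates only -- the second strategy for pragmatic model performance.

#' @keywords internal
pattern_id_of <- function(pattern) paste(pattern, collapse = "+")

#' Enumerate observed-covariate patterns
#'
#' Returns the distinct observed-covariate subsets present in the data.
#' Every pattern contains all always-observed covariates; patterns are
#' sorted by subset size descending (full pattern first), ties
#' lexicographically. Pattern identity ignores auxiliary variables outside
#' the model formula.
#'
#' @param mdata A `missing_data` object.
#' @param always_observed Covariates guaranteed complete (default: those
#'   with no masked cells).
#' @return List of character vectors (covariate subsets in canonical order),
#'   named by their pattern id.
#' @export
enumerate_patterns <- function(mdata, always_observed = NULL) {
  covs <- intersect(model_covariates(mdata$specs), names(mdata$data))
  if (is.null(always_observed)) {
    always_observed <- covs[colSums(mdata$mask[, covs, drop = FALSE]) == 0L]
  }
  if (any(colSums(mdata$mask[, always_observed, drop = FALSE]) > 0L)) {
    stop("always_observed covariates have masked cells")
  }
  ids <- unique(mdata$pattern_id)
  patterns <- lapply(ids, function(id) strsplit(id, "+", fixed = TRUE)[[1L]])
  bad <- !vapply(patterns, function(p) all(always_observed %in% p), TRUE)
  if (any(bad)) {
    stop("pattern(s) smaller than the always-observed set: ",
         paste(ids[bad], collapse = "; "))
  }
  ord <- order(-lengths(patterns), ids)
  patterns <- patterns[ord]
  names(patterns) <- ids[ord]
  patterns
}

#' Fit the full and partial prediction models
#'
#' Fits one model per observed-covariate pattern -- each to *all*
#' individuals of every imputed dataset in the primary stack, not to the
#' pattern's own subset -- and pools coefficients by Rubin's rules.
#'
#' @param stack The primary `imputed_stack` (outcome included in the
#'   imputation models).
#' @param patterns Pattern list from [enumerate_patterns()].
#' @param link `"identity"` or `"logit"`.
#' @return A `pattern_model_set`: list with `patterns`, `models` (named list
#'   of `coefficient_set`s) and `link`.
#' @export
fit_pattern_models <- function(stack, patterns,
                               link = c("identity", "logit")) {
  link <- match.arg(link)
  stopifnot(inherits(stack, "imputed_stack"))
  if (!stack$include_outcome) {
    stop("partial models must be fitted on the primary (outcome-included) ",
         "stack")
  }
  models <- lapply(patterns, function(p) {
    fit_per_imputation(stack, covariates = p, link = link,
                       specs = stack$specs)
  })
  names(models) <- names(patterns)
  structure(list(patterns = patterns, models = models, link = link),
            class = "pattern_model_set")
}

#' Predictions from routed partial models
#'
#' Each individual is routed to the model whose covariate set equals their
#' observed covariates, and the prediction uses observed values only --
#' imputed cells are never read. Replicated over imputations
#' (`imputation_specific`, P1-style, one column per coefficient vector) or a
#' single column under pooled coefficients; all rows are covered.
#'
#' @param models A `pattern_model_set`.
#' @param mdata The `missing_data` object to predict for.
#' @param coef_mode `"imputation_specific"` or `"pooled"`.
#' @return A `prediction_set` labelled `"P1"` covering all rows.
#' @export
predict_partial <- function(models, mdata,
                            coef_mode = c("imputation_specific", "pooled")) {
  coef_mode <- match.arg(coef_mode)
  stopifnot(inherits(models, "pattern_model_set"),
            inherits(mdata, "missing_data"))
  unseen <- setdiff(unique(mdata$pattern_id), names(models$models))
  if (length(unseen)) {
    stop("no fitted model for observed pattern(s): ",
         paste(unseen, collapse = "; "))
  }
  obs_df <- as_observed(mdata)
  n <- nrow(obs_df)
  M <- models$models[[1L]]$M
  R <- if (coef_mode == "pooled") 1L else M
  lp <- matrix(NA_real_, n, R)
  for (id in unique(mdata$pattern_id)) {
    rows <- which(mdata$pattern_id == id)
    cs <- models$models[[id]]
    X <- design_matrix(obs_df[rows, , drop = FALSE], cs$covariates,
                       cs$specs)
    if (anyNA(X)) stop("internal error: routed design touched a masked cell")
    if (coef_mode == "pooled") {
      lp[rows, 1L] <- drop(X %*% cs$pooled)
    } else {
      for (k in seq_len(M)) lp[rows, k] <- drop(X %*% cs$coef[k, ])
    }
  }
  prediction_set(lp, "P1", coef_mode, seq_len(n), models$link,
                 replicate_index = data.frame(k = seq_len(R)))
}
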