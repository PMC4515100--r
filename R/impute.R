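# Multiple imputation by chained equations with predictive mean matching.
#
# Each incomplete continuous variable is imputed on its modelling
# (transformed) scale by a Bayesian linear regression draw followed by donor
# matching; the donor's natural-scale value is copied, so observed values are
# the only values ever imputed.

#' Predictive-mean-matching draw
#'
#' Fits the regression of `y_obs` on `X_obs`; draws the residual variance
#' from its scaled inverse chi-squared posterior and the coefficient vector
#' from its Normal posterior; computes donor predictions `X_obs %*% beta_hat`
#' and recipient predictions `X_mis %*% beta_star`; for each recipient,
#' selects uniformly among the `donors` observed cases with closest donor
#' prediction and returns that donor's observed value (type-1 matching).
#'
#' @param y_obs Observed values of the target variable.
#' @param X_obs Design rows of the observed cases.
#' @param X_mis Design rows of the recipients.
#' @param donors Donor-pool size (default 5).
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param posterior_draw If `FALSE`, skip the posterior perturbation and use
#'   the least-squares fit for recipients too (deterministic matching, used
#'   for testing).
#' @return Numeric vector of imputed values, one per row of `X_mis`, with
#'   the chosen donor row indices in attribute `"donor"`.
#' @export
pmm_draw <- function(y_obs, X_obs, X_mis, donors = 5L, seed = NULL,
                     posterior_draw = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  X_obs <- as.matrix(X_obs)
  X_mis <- as.matrix(X_mis)
  n <- length(y_obs)
  if (nrow(X_obs) != n) stop("y_obs and X_obs disagree on rows")
  if (donors < 1 || donors > n) {
    stop("donors must lie between 1 and the number of observed cases")
  }
  if (n < ncol(X_obs) + 1L) stop("fewer observed cases than parameters + 1")

  qrX <- qr(X_obs)
  if (qrX$rank < ncol(X_obs)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    warning("dropping collinear design column(s): ",
            paste(colnames(X_obs)[-keep], collapse = ", "))
    X_obs <- X_obs[, keep, drop = FALSE]
    X_mis <- X_mis[, keep, drop = FALSE]
    qrX <- qr(X_obs)
  }
  beta_hat <- qr.coef(qrX, y_obs)
  res <- y_obs - drop(X_obs %*% beta_hat)
  p <- qrX$rank
  df <- n - p

  beta_star <- beta_hat
  if (posterior_draw && df > 0) {
    sigma2_star <- sum(res^2) / stats::rchisq(1L, df)
    U <- chol(chol2inv(chol(crossprod(X_obs))))
    beta_star <- beta_hat +
      sqrt(sigma2_star) * drop(crossprod(U, stats::rnorm(p)))
  }

  pred_obs <- drop(X_obs %*% beta_hat)
  pred_mis <- drop(X_mis %*% beta_star)

  # the `donors` nearest donor predictions lie within `donors` sorted
  # positions of the recipient's insertion point, so a constant-width window
  # around it suffices; ties broken at random (max.col)
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  pos <- findInterval(pred_mis, po)
  m <- nrow(X_mis)
  w <- min(n, 2L * donors + 1L)
  lo <- pmax(1L, pmin(pos - donors, n - w + 1L))
  cand <- outer(lo, 0L:(w - 1L), "+")
  D <- abs(matrix(po[cand], nrow = m) - pred_mis)
  picks <- matrix(0L, m, donors)
  rows <- seq_len(m)
  for (t in seq_len(donors)) {
    j <- max.col(-D, ties.method = "random")
    picks[, t] <- cand[cbind(rows, j)]
    D[cbind(rows, j)] <- Inf
  }
  choice <- if (donors == 1L) picks[, 1L] else {
    picks[cbind(rows, sample.int(donors, m, replace = TRUE))]
  }
  donor_idx <- ord[choice]
  structure(y_obs[donor_idx], donor = donor_idx)
}

#' Chained-equations multiple imputation with PMM
#'
#' Produces `M` completed copies of a [missing_data] object. Within each of
#' the `M` independent chains (each with its own sub-seed derived from
#' `seed`): missing values are initialised by random draws from each
#' variable's observed values; incomplete variables are then visited in order
#' of increasing missingness for `iterations` full cycles, each visit
#' refitting the conditional model of the variable (on its transformed scale)
#' given all other model covariates -- plus the outcome if and only if
#' `include_outcome` -- and imputing by [pmm_draw()]. Stacks built with the
#' outcome are tagged `"primary"` (used to derive the prediction model);
#' stacks built without it are tagged `"secondary"` (used to imitate a future
#' clinical setting where the outcome is unknown).
#'
#' @param mdata A `missing_data` object (outcome fully observed).
#' @param M Number of imputations (>= 1).
#' @param iterations Burn-in cycles per chain (default 10).
#' @param donors PMM donor-pool size (default 5; set 1 to mimic older
#'   software defaults).
#' @param include_outcome Should the outcome enter the conditional models?
#' @param seed Master integer seed; `M`, the configuration and `seed` fully
#'   determine the output.
#' @return An `imputed_stack`: list with `datasets` (list of `M` completed
#'   data frames), `M`, `include_outcome`, `provenance`, `seed` and `mask`.
#' @export
impute_chained <- function(mdata, M = 5L, iterations = 10L, donors = 5L,
                           include_outcome = TRUE, seed = 1L) {
  stopifnot(inherits(mdata, "missing_data"), M >= 1, iterations >= 1,
            donors >= 1)
  specs <- mdata$specs
  covs <- intersect(model_covariates(specs), names(mdata$data))
  miss_counts <- colSums(mdata$mask[, covs, drop = FALSE])
  vars <- names(sort(miss_counts[miss_counts > 0]))
  obs_df <- as_observed(mdata)
  if (include_outcome && !"y" %in% names(obs_df)) {
    stop("include_outcome = TRUE but no outcome column 'y' present")
  }

  impute_one <- function(chain_seed) {
    set.seed(chain_seed)
    df <- obs_df
    for (v in vars) {
      mis <- mdata$mask[, v]
      obs_vals <- df[[v]][!mis]
      if (!length(obs_vals)) stop("no observed donors for variable '", v, "'")
      df[[v]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
    }
    # design over all covariate terms, maintained in place across visits
    X_all <- design_matrix(df, covs, specs)
    if (include_outcome) X_all <- cbind(X_all, y = df$y)
    term_of <- vapply(vars, function(v) term_names(specs[[v]]), "")
    for (it in seq_len(iterations)) {
      for (v in vars) {
        mis <- mdata$mask[, v]
        f <- transform_fn(specs[[v]]$transform)
        target <- f(df[[v]])
        drop_col <- match(term_of[[v]], colnames(X_all))
        X <- X_all[, -drop_col, drop = FALSE]
        imp <- suppressWarnings(
          pmm_draw(target[!mis], X[!mis, , drop = FALSE],
                   X[mis, , drop = FALSE], donors = donors)
        )
        donor_rows <- which(!mis)[attr(imp, "donor")]
        df[[v]][mis] <- df[[v]][donor_rows]
        X_all[mis, drop_col] <- f(df[[v]][mis])
      }
    }
    df
  }

  datasets <- lapply(seq_len(M), function(k) {
    if (!length(vars)) obs_df else impute_one(derive_seed(seed, k))
  })
  structure(
    list(datasets = datasets, M = as.integer(M),
         include_outcome = include_outcome,
         provenance = if (include_outcome) "primary" else "secondary",
         seed = seed, mask = mdata$mask, specs = specs),
    class = "imputed_stack"
  )
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("imputed_stack: M =", x$M, "|", x$provenance,
      if (x$include_outcome) "(outcome in imputation models)"
      else "(outcome excluded)", "\n")
  invisible(x)
}
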