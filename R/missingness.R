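# Missingness mechanisms: independent MCAR, monotone MCAR, and the staged
# monotone MAR mechanism driven by a logistic model for an auxiliary
# missingness indicator. Outcomes are never deleted.

#' Construct a missing-data object
#'
#' Pairs the underlying complete data with a logical mask (`TRUE` = deleted)
#' and a per-row identifier of the observed-covariate pattern. The complete
#' values are retained so simulation code can compare against the truth;
#' analysis code must go through [as_observed()].
#'
#' @param data Complete data frame (must contain no `NA`).
#' @param mask Logical matrix, same dimensions and column names as `data`.
#' @return A `missing_data` object.
#' @export
missing_data <- function(data, mask) {
  stopifnot(is.data.frame(data), is.logical(mask),
            nrow(mask) == nrow(data), ncol(mask) == ncol(data))
  colnames(mask) <- names(data)
  if ("y" %in% names(data) && any(mask[, "y"])) {
    stop("the outcome column must never be masked")
  }
  specs <- attr(data, "specs")
  if (is.null(specs)) specs <- uk700_specs()
  covs <- intersect(model_covariates(specs), names(data))
  pattern_id <- apply(!mask[, covs, drop = FALSE], 1L, function(obs) {
    paste(covs[obs], collapse = "+")
  })
  structure(list(data = data, mask = mask, pattern_id = pattern_id,
                 specs = specs),
            class = "missing_data")
}

#' Observed view of a missing-data object
#' @param mdata A `missing_data` object.
#' @return Data frame with `NA` in every masked cell.
#' @export
as_observed <- function(mdata) {
  df <- mdata$data
  for (v in names(df)) {
    if (any(mdata$mask[, v])) df[[v]][mdata$mask[, v]] <- NA
  }
  attr(df, "specs") <- mdata$specs
  df
}

#' @keywords internal
empty_mask <- function(data) {
  m <- matrix(FALSE, nrow(data), ncol(data))
  colnames(m) <- names(data)
  m
}

#' @keywords internal
check_deletable <- function(data, vars) {
  if ("y" %in% vars) stop("cannot induce missingness in the outcome")
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "))
  }
}

#' Independent MCAR deletion
#'
#' Deletes, for each named variable, exactly `round(rate * n)` values
#' (half-up rounding), selected uniformly without replacement and
#' independently across variables. The canonical scenario deletes 30% of
#' `cprs0` and 10% each of `onset` and `distot`.
#'
#' @param data Complete data frame.
#' @param rates Named numeric vector or list, variable -> deletion fraction
#'   in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `missing_data` object.
#' @export
apply_independent_mcar <- function(data,
                                   rates = c(cprs0 = 0.3, onset = 0.1,
                                             distot = 0.1),
                                   seed = 1L) {
  rates <- unlist(rates)
  check_deletable(data, names(rates))
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  set.seed(seed)
  n <- nrow(data)
  mask <- empty_mask(data)
  for (v in names(rates)) {
    k <- round_half_up(rates[[v]] * n)
    if (k > 0) mask[sample.int(n, k), v] <- TRUE
  }
  missing_data(data, mask)
}

#' Monotone MCAR deletion
#'
#' Forms three disjoint random subgroups each of size `round(0.1 * n)`:
#' `distot` is deleted in the first subgroup, `onset` in the first two and
#' `cprs0` in all three, producing a monotone pattern (missing `distot`
#' implies missing `onset` implies missing `cprs0`) with 30% of `cprs0`
#' deleted completely at random.
#'
#' @param data Complete data frame.
#' @param seed Integer seed.
#' @return A `missing_data` object.
#' @export
apply_monotone_mcar <- function(data, seed = 1L) {
  n <- nrow(data)
  if (n < 10) stop("n must be >= 10 (subgroups of size round(0.1 n) empty)")
  check_deletable(data, c("cprs0", "onset", "distot"))
  set.seed(seed)
  g <- round_half_up(0.1 * n)
  idx <- sample.int(n, 3L * g)
  g1 <- idx[seq_len(g)]
  g2 <- idx[g + seq_len(g)]
  g3 <- idx[2L * g + seq_len(g)]
  mask <- empty_mask(data)
  mask[g1, "distot"] <- TRUE
  mask[c(g1, g2), "onset"] <- TRUE
  mask[c(g1, g2, g3), "cprs0"] <- TRUE
  missing_data(data, mask)
}

#' Specification of one MAR deletion stage
#'
#' @param drivers Covariates of the stage's logistic missingness model.
#' @param fraction Share of the highest fitted probabilities to delete
#'   (strictly between 0 and 1).
#' @param delete Variables deleted at this stage.
#' @return A `mar_stage` object.
#' @export
mar_stage <- function(drivers, fraction, delete) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  structure(list(drivers = drivers, fraction = fraction, delete = delete),
            class = "mar_stage")
}

#' Canonical staged-MAR stage lists
#'
#' The 30% scenario deletes the top tenth, ninth and eighth of the remaining
#' individuals at stages 1--3 (10% + 10% + 10% of `cprs0`); the 60% scenario
#' uses the top fifth, quarter and third (20% + 20% + 20%). Stage models
#' regress the auxiliary `occgp_missing` indicator on age, sex, status, with
#' `distot` added at stage 2 and `onset` at stage 3; centre is deliberately
#' excluded.
#'
#' @param target `"30"` or `"60"` (percent missingness induced in `cprs0`).
#' @return List of [mar_stage()] objects.
#' @export
mar_stages <- function(target = c("30", "60")) {
  target <- match.arg(target)
  f <- if (target == "30") c(1 / 10, 1 / 9, 1 / 8) else c(1 / 5, 1 / 4, 1 / 3)
  list(
    mar_stage(c("age", "sex", "status"), f[1L],
              c("cprs0", "onset", "distot")),
    mar_stage(c("distot", "age", "sex", "status"), f[2L],
              c("cprs0", "onset")),
    mar_stage(c("onset", "distot", "age", "sex", "status"), f[3L],
              "cprs0")
  )
}

#' Staged monotone MAR deletion
#'
#' At each stage a logistic regression of the auxiliary indicator on the
#' stage's driver covariates is fitted among individuals untouched by earlier
#' stages; the stage's variables are deleted for the `fraction` of remaining
#' individuals with the highest fitted probabilities (ties broken by a seeded
#' random jitter of the rank order). Because later-stage drivers include
#' variables already deleted for earlier-stage individuals, the resulting
#' pattern is monotone and missing-at-random given the observed covariates.
#'
#' @param data Complete data frame containing the binary auxiliary column.
#' @param stages List of [mar_stage()] objects; default [mar_stages("30")].
#' @param auxiliary Name of the binary auxiliary outcome column.
#' @param seed Integer seed (tie-breaking jitter only; the mechanism is
#'   otherwise deterministic given the data).
#' @return A `missing_data` object.
#' @export
apply_staged_mar <- function(data, stages = mar_stages("30"),
                             auxiliary = "occgp_missing", seed = 1L) {
  if (!length(stages)) stop("stages must be non-empty")
  if (!auxiliary %in% names(data)) {
    stop("auxiliary column '", auxiliary, "' not found")
  }
  specs <- attr(data, "specs")
  if (is.null(specs)) specs <- uk700_specs()
  set.seed(seed)
  mask <- empty_mask(data)
  remaining <- seq_len(nrow(data))
  for (st in stages) {
    check_deletable(data, st$delete)
    missing_drivers <- setdiff(st$drivers, names(data))
    if (length(missing_drivers)) {
      stop("driver variable(s) not in data: ",
           paste(missing_drivers, collapse = ", "))
    }
    X <- design_matrix(data[remaining, , drop = FALSE], st$drivers, specs)
    fit <- stats::glm.fit(X, data[[auxiliary]][remaining],
                          family = stats::binomial())
    if (!fit$converged) stop("stage missingness model failed to converge")
    p <- fit$fitted.values
    k <- round_half_up(st$fraction * length(remaining))
    ord <- order(p, stats::runif(length(p)), decreasing = TRUE)
    hit <- remaining[ord[seq_len(k)]]
    mask[hit, st$delete] <- TRUE
    remaining <- setdiff(remaining, hit)
  }
  missing_data(data, mask)
}
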