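# Per-imputation GLM fitting and Rubin's-rules pooling of coefficients.

#' Pool estimates by Rubin's rules
#'
#' Pooled estimate = componentwise mean of the per-imputation estimates;
#' within-imputation variance `W` = mean of the per-imputation covariance
#' matrices; between-imputation variance `B` = sample covariance of the
#' estimates (denominator `M - 1`; the zero matrix when `M = 1`); total
#' variance `T = W + (1 + 1/M) B`. The small-sample degrees of freedom
#' `nu = (M - 1) (1 + W / ((1 + 1/M) B))^2` are returned per term.
#'
#' @param estimates List of equal-length coefficient vectors (or a matrix
#'   with one row per imputation).
#' @param covariances Optional list of covariance matrices, one per
#'   imputation; zero matrices assumed when omitted.
#' @return List with `pooled`, `W`, `B`, `T` (matrices) and `nu`.
#' @export
pool_coefficients <- function(estimates, covariances = NULL) {
  if (is.list(estimates)) {
    lens <- lengths(estimates)
    if (length(unique(lens)) != 1L) stop("estimates differ in length")
    est <- do.call(rbind, estimates)
  } else {
    est <- as.matrix(estimates)
  }
  M <- nrow(est)
  p <- ncol(est)
  if (M < 1L) stop("need at least one estimate")
  if (is.null(covariances)) {
    covariances <- replicate(M, matrix(0, p, p), simplify = FALSE)
  }
  if (length(covariances) != M) stop("one covariance per estimate required")
  pooled <- colMeans(est)
  W <- Reduce(`+`, covariances) / M
  B <- if (M == 1L) matrix(0, p, p) else stats::cov(est)
  Tm <- W + (1 + 1 / M) * B
  dW <- diag(as.matrix(W))
  dB <- diag(as.matrix(B))
  nu <- ifelse(dB > 0, (M - 1) * (1 + dW / ((1 + 1 / M) * dB))^2, Inf)
  names(pooled) <- colnames(est)
  list(pooled = pooled, W = W, B = B, T = Tm, nu = nu)
}

#' @keywords internal
fit_glm_matrix <- function(X, y, link) {
  p <- ncol(X)
  if (link == "identity") {
    qrX <- qr(X)
    if (qrX$rank < p) {
      aliased <- colnames(X)[-sort(qrX$pivot[seq_len(qrX$rank)])]
      stop("rank-deficient design; aliased term(s): ",
           paste(aliased, collapse = ", "))
    }
    beta <- qr.coef(qrX, y)
    res <- y - drop(X %*% beta)
    sigma2 <- sum(res^2) / (length(y) - p)
    V <- sigma2 * chol2inv(chol(crossprod(X)))
  } else {
    if (length(unique(y)) < 2L) stop("outcome has a single class")
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(maxit = 100L,
                                                  epsilon = 1e-8))
    )
    if (!fit$converged) stop("logistic fit failed to converge")
    if (any(is.na(fit$coefficients))) {
      aliased <- colnames(X)[is.na(fit$coefficients)]
      stop("rank-deficient design; aliased term(s): ",
           paste(aliased, collapse = ", "))
    }
    beta <- fit$coefficients
    V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  }
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = V)
}

#' Fit the prediction model to each imputed dataset and pool
#'
#' One maximum-likelihood GLM fit per completed dataset (ordinary least
#' squares for the identity link, IRLS logistic regression for the logit
#' link), with coefficients in a fixed term order across imputations, then
#' Rubin's-rules pooling via [pool_coefficients()].
#'
#' @param stack An `imputed_stack`, or a single complete data frame (treated
#'   as an `M = 1` stack).
#' @param covariates Covariate column names entering the model (default: all
#'   model covariates in the spec catalogue).
#' @param link `"identity"` or `"logit"`.
#' @param specs Spec catalogue.
#' @return A `coefficient_set`: list with `terms`, `link`, per-imputation
#'   coefficient matrix `coef` (M x p), `vcov` list, and pooled `pooled`,
#'   `W`, `B`, `T`, `nu`, `M`.
#' @export
fit_per_imputation <- function(stack, covariates = NULL,
                               link = c("identity", "logit"),
                               specs = uk700_specs()) {
  link <- match.arg(link)
  if (is.data.frame(stack)) {
    stack <- list(datasets = list(stack), M = 1L)
  }
  if (is.null(covariates)) {
    covariates <- intersect(model_covariates(specs),
                            names(stack$datasets[[1L]]))
  }
  fits <- lapply(seq_len(stack$M), function(k) {
    df <- stack$datasets[[k]]
    if (!"y" %in% names(df)) stop("no outcome column 'y' in imputation ", k)
    X <- design_matrix(df, covariates, specs)
    tryCatch(fit_glm_matrix(X, df$y, link),
             error = function(e) {
               stop("fit failed in imputation ", k, ": ",
                    conditionMessage(e))
             })
  })
  coef_mat <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  vcovs <- lapply(fits, `[[`, "vcov")
  pooled <- pool_coefficients(
    lapply(seq_len(nrow(coef_mat)), function(k) coef_mat[k, ]), vcovs)
  structure(
    list(terms = colnames(coef_mat), covariates = covariates, link = link,
         coef = coef_mat, vcov = vcovs, pooled = pooled$pooled,
         W = pooled$W, B = pooled$B, T = pooled$T, nu = pooled$nu,
         M = stack$M, specs = specs),
    class = "coefficient_set"
  )
}

#' @export
print.coefficient_set <- function(x, digits = 4, ...) {
  cat("coefficient_set:", x$link, "link, M =", x$M, "\n")
  print(round(x$pooled, digits))
  invisible(x)
}

#' Serialize a coefficient set to JSON
#'
#' @param x A `coefficient_set`.
#' @param path Output file path.
#' @return `path`, invisibly. Requires the `jsonlite` package.
#' @export
write_coefficient_set <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for JSON export")
  }
  obj <- list(terms = x$terms, link = x$link, M = x$M,
              per_imputation = unname(apply(x$coef, 1L, as.list)),
              pooled = as.list(x$pooled),
              W_diag = diag(as.matrix(x$W)),
              B_diag = diag(as.matrix(x$B)),
              T_diag = diag(as.matrix(x$T)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
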