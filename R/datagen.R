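# Synthetic covariate generation and outcome simulation.
#
# The joint covariate distribution of the original trial is not public; a
# Gaussian copula with a single exchangeable latent correlation reproduces the
# published marginals while keeping the covariates mutually correlated and
# univariately predictive.

#' Generate synthetic trial-like covariates
#'
#' Draws `n` individuals whose marginals match the published baseline table:
#' continuous covariates are generated directly on their transformed
#' (modelling) scale and stored back-transformed on the natural scale; `age`
#' is truncated to 18--65 by redrawing its idiosyncratic latent component;
#' binaries and the four-level `centre` are obtained by thresholding latent
#' normals that share the same exchangeable copula factor. The auxiliary
#' indicator `occgp_missing` (prevalence ~19%) is drawn from a fixed logistic
#' model in age, sex and status (coefficients 0.03, -0.4, 0.5; intercept
#' -2.67) and later serves as the outcome of the MAR missingness models.
#'
#' @param n Number of individuals (>= 1).
#' @param correlation Exchangeable latent correlation in `[0, 1)` shared by
#'   all covariates (default 0.2).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param specs Variable catalogue; defaults to [uk700_specs()].
#' @return A `data.frame` with columns `cprs0`, `age`, `onset`, `distot`,
#'   `sex`, `status`, `centre` (factor) and `occgp_missing`, carrying the
#'   spec catalogue in attribute `"specs"`.
#' @export
generate_covariates <- function(n, correlation = 0.2, seed = 1L,
                                specs = uk700_specs()) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  if (correlation < 0 || correlation >= 1) {
    stop("correlation must lie in [0, 1)")
  }
  n <- as.integer(n)
  set.seed(seed)

  # exchangeable Gaussian copula: z_d = sqrt(rho) w + sqrt(1-rho) e_d
  d <- 7L
  w <- stats::rnorm(n)
  z <- sqrt(correlation) * w +
    sqrt(1 - correlation) * matrix(stats::rnorm(n * d), n, d)

  draw_cont <- function(j, sp) sp$mean + sp$sd * z[, j]

  t_cprs0 <- draw_cont(1L, specs$cprs0)
  age <- draw_cont(2L, specs$age)
  t_onset <- draw_cont(3L, specs$onset)
  t_distot <- draw_cont(4L, specs$distot)

  # truncate age by redrawing only its idiosyncratic component, keeping the
  # shared factor so the copula coupling survives truncation
  b <- specs$age$bounds
  repeat {
    bad <- which(age < b[1L] | age > b[2L])
    if (!length(bad)) break
    age[bad] <- specs$age$mean + specs$age$sd *
      (sqrt(correlation) * w[bad] +
         sqrt(1 - correlation) * stats::rnorm(length(bad)))
  }

  sex <- as.integer(z[, 5L] < stats::qnorm(specs$sex$probs))
  status <- as.integer(z[, 6L] < stats::qnorm(specs$status$probs))

  u <- stats::pnorm(z[, 7L])
  cuts <- cumsum(specs$centre$probs)
  centre <- factor(specs$centre$levels[1L + findInterval(u, cuts[-length(cuts)])],
                   levels = specs$centre$levels)

  lp_occ <- -2.67 + 0.03 * age - 0.4 * sex + 0.5 * status
  occgp_missing <- stats::rbinom(n, 1L, expit(lp_occ))

  out <- data.frame(
    cprs0 = expm1(t_cprs0),
    age = age,
    onset = exp(t_onset),
    distot = exp(t_distot),
    sex = sex,
    status = status,
    centre = centre,
    occgp_missing = occgp_missing
  )
  attr(out, "specs") <- specs
  out
}

#' Built-in outcome-generating models
#'
#' Returns one of the four published generating models for the simulated
#' symptom-score outcome: the linear model for `log(cprs + 1)` (Gaussian
#' noise variance 0.61), its strong-predictor variant with the `cprs0`
#' coefficient doubled from 0.34 to 0.68, and the two logistic models for the
#' dichotomized outcomes `cprs > 25` (prevalence ~26%) and `cprs > 40`
#' (prevalence ~9%).
#'
#' @param name One of `"linear"`, `"linear_strong"`, `"logistic_25"`,
#'   `"logistic_8"`.
#' @return A `generating_model`: list with `link` (`"identity"` or
#'   `"logit"`), named `coefficients` (including `"(Intercept)"`), `sigma2`
#'   (identity link only) and `label`.
#' @export
builtin_model <- function(name = c("linear", "linear_strong",
                                   "logistic_25", "logistic_8")) {
  name <- match.arg(name)
  terms <- c("(Intercept)", "log1p_cprs0", "age", "log_onset", "log_distot",
             "sex", "status", "centre2", "centre3", "centre4")
  coefs <- switch(
    name,
    linear = c(1.64, 0.34, -0.01, 0.11, 0.20, -0.19, 0.15,
               0.06, 0.30, 0.0008),
    linear_strong = c(1.64, 0.68, -0.01, 0.11, 0.20, -0.19, 0.15,
                      0.06, 0.30, 0.0008),
    logistic_25 = c(-3.20, 0.75, -0.03, 0.25, 0.44, -0.28, -0.14,
                    -0.29, 0.91, 0.16),
    logistic_8 = c(-6.54, 1.13, -0.04, 0.37, 0.51, -0.50, -0.07,
                   -0.63, 1.55, 0.86)
  )
  names(coefs) <- terms
  link <- if (name %in% c("linear", "linear_strong")) "identity" else "logit"
  generating_model(link, coefs,
                   sigma2 = if (link == "identity") 0.61 else NULL,
                   label = name)
}

#' Construct a generating model
#'
#' @param link `"identity"` or `"logit"`.
#' @param coefficients Named coefficient vector including `"(Intercept)"`.
#' @param sigma2 Gaussian noise *variance* (identity link only; must be
#'   >= 0). Logit-link models take no noise term.
#' @param label Free-text label.
#' @return A `generating_model` object.
#' @export
generating_model <- function(link = c("identity", "logit"), coefficients,
                             sigma2 = NULL, label = "") {
  link <- match.arg(link)
  if (!"(Intercept)" %in% names(coefficients)) {
    stop("coefficient map must include an intercept")
  }
  if (link == "identity") {
    if (is.null(sigma2) || sigma2 < 0) {
      stop("identity link requires a noise variance sigma2 >= 0")
    }
  } else if (!is.null(sigma2)) {
    stop("logit link has no noise term")
  }
  structure(list(link = link, coefficients = coefficients,
                 sigma2 = sigma2, label = label),
            class = "generating_model")
}

#' Evaluate a generating model's linear predictor
#' @keywords internal
model_linear_predictor <- function(data, model, specs = uk700_specs()) {
  covs <- model_covariates(specs)
  X <- design_matrix(data, covs, specs)
  beta <- model$coefficients
  missing_terms <- setdiff(names(beta), colnames(X))
  if (length(missing_terms)) {
    stop("model terms not resolvable from data: ",
         paste(missing_terms, collapse = ", "))
  }
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' Simulate an outcome column from a generating model
#'
#' Appends a column `y` on the modelling scale: for the identity link,
#' the linear predictor plus Gaussian noise with variance `sigma2`; for the
#' logit link, a Bernoulli draw with probability `expit(linear predictor)`.
#'
#' @param data Covariate data frame from [generate_covariates()].
#' @param model A `generating_model`, e.g. [builtin_model()].
#' @param seed Integer seed for the noise / Bernoulli draws.
#' @return `data` with an added numeric column `y`; the model's link is
#'   stored in attribute `"outcome_link"`.
#' @export
simulate_outcome <- function(data, model, seed = 1L) {
  specs <- attr(data, "specs")
  if (is.null(specs)) specs <- uk700_specs()
  lp <- model_linear_predictor(data, model, specs)
  set.seed(seed)
  y <- if (model$link == "identity") {
    lp + stats::rnorm(nrow(data), 0, sqrt(model$sigma2))
  } else {
    stats::rbinom(nrow(data), 1L, expit(lp))
  }
  data$y <- y
  attr(data, "specs") <- specs
  attr(data, "outcome_link") <- model$link
  data
}
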