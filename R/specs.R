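#' Variable metadata for a rectangular analysis dataset
#'
#' A `variable_spec` records, for one column, its role in the prediction
#' problem (outcome, covariate, auxiliary), its storage type, the transform
#' applied before modelling, and its marginal parameters on the *transformed*
#' scale (mean and SD for continuous variables, category probabilities
#' otherwise).
#'
#' @param name Column name.
#' @param role One of `"covariate"`, `"outcome"`, `"auxiliary"`.
#' @param dtype One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param transform Transform applied before the variable enters a model:
#'   `"none"`, `"log"` or `"log1p"`. Only continuous variables may be
#'   transformed.
#' @param mean,sd Marginal mean and SD on the transformed scale
#'   (continuous variables only; `sd` must be positive).
#' @param probs For binary variables the probability of the value 1; for
#'   categorical variables a vector of category probabilities summing to 1.
#' @param levels Category labels (categorical variables only).
#' @param bounds Optional length-2 numeric vector of truncation bounds on the
#'   natural scale.
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name,
                          role = c("covariate", "outcome", "auxiliary"),
                          dtype = c("continuous", "binary", "categorical"),
                          transform = c("none", "log", "log1p"),
                          mean = NULL, sd = NULL, probs = NULL,
                          levels = NULL, bounds = NULL) {
  role <- match.arg(role)
  dtype <- match.arg(dtype)
  transform <- match.arg(transform)
  if (dtype != "continuous" && transform != "none") {
    stop("transform '", transform, "' is only valid for continuous variables")
  }
  if (dtype == "continuous") {
    if (is.null(mean) || is.null(sd)) {
      stop("continuous variable '", name, "' needs mean and sd")
    }
    if (sd <= 0) stop("sd must be > 0 for variable '", name, "'")
  }
  if (dtype == "binary") {
    if (is.null(probs) || length(probs) != 1L || probs < 0 || probs > 1) {
      stop("binary variable '", name, "' needs a single probability in [0,1]")
    }
  }
  if (dtype == "categorical") {
    if (is.null(probs) || is.null(levels) || length(probs) != length(levels)) {
      stop("categorical variable '", name, "' needs matching probs and levels")
    }
    if (abs(sum(probs) - 1) > 1e-12) {
      stop("category probabilities of '", name, "' must sum to 1")
    }
  }
  structure(
    list(name = name, role = role, dtype = dtype, transform = transform,
         mean = mean, sd = sd, probs = probs, levels = levels,
         bounds = bounds),
    class = "variable_spec"
  )
}

#' Variable catalogue for the synthetic psychiatric-trial dataset
#'
#' Marginal parameters follow the published baseline table of the UK700
#' multicentre trial of case-management intensity in psychosis (n = 708):
#' baseline symptom score `cprs0` (log1p scale mean 2.73, SD 0.82), time from
#' onset of psychosis `onset` (log scale 4.62, 0.98), total disability
#' `distot` (log scale -0.07, 0.81), `age` truncated to the trial's 18--65
#' range, `sex` (1 = male, 57%), outpatient `status` (1 = outpatient, 59%),
#' recruitment `centre` with four levels in proportions 196/158/201/153, and
#' the auxiliary indicator `occgp_missing` (missing father's occupation,
#' ~19%) which drives the MAR missingness mechanism.
#'
#' @return Named list of [variable_spec] objects.
#' @export
uk700_specs <- function() {
  specs <- list(
    variable_spec("cprs0", "covariate", "continuous", "log1p",
                  mean = 2.73, sd = 0.82),
    variable_spec("age", "covariate", "continuous", "none",
                  mean = 38.29, sd = 11.64, bounds = c(18, 65)),
    variable_spec("onset", "covariate", "continuous", "log",
                  mean = 4.62, sd = 0.98),
    variable_spec("distot", "covariate", "continuous", "log",
                  mean = -0.07, sd = 0.81),
    variable_spec("sex", "covariate", "binary", probs = 404 / 708),
    variable_spec("status", "covariate", "binary", probs = 418 / 707),
    variable_spec("centre", "covariate", "categorical",
                  probs = c(196, 158, 201, 153) / 708,
                  levels = c("1", "2", "3", "4")),
    variable_spec("occgp_missing", "auxiliary", "binary", probs = 132 / 708)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' @keywords internal
transform_fn <- function(transform) {
  switch(transform,
         none = identity,
         log = log,
         log1p = log1p,
         stop("unknown transform '", transform, "'"))
}

#' @keywords internal
inverse_transform_fn <- function(transform) {
  switch(transform,
         none = identity,
         log = exp,
         log1p = expm1,
         stop("unknown transform '", transform, "'"))
}

#' Model-term name of a variable under its spec
#'
#' Continuous variables with a transform get a prefixed term name
#' (e.g. `log1p_cprs0`); others keep their column name. Categorical
#' variables expand to one term per non-reference level (`centre2`, ...).
#'
#' @param spec A [variable_spec].
#' @return Character vector of term names.
#' @export
term_names <- function(spec) {
  if (spec$dtype == "categorical") {
    return(paste0(spec$name, spec$levels[-1L]))
  }
  switch(spec$transform,
         none = spec$name,
         paste0(spec$transform, "_", spec$name))
}

#' Names of the model covariates in a spec catalogue
#' @param specs Named list of [variable_spec]s.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(specs = uk700_specs()) {
  names(specs)[vapply(specs, function(s) s$role == "covariate", TRUE)]
}

#' Build a design matrix from raw columns
#'
#' Applies each covariate's transform, dummy-codes categorical variables
#' against their first (reference) level and prepends an intercept. The
#' reference coding matters: the shipped generating models use centre level 1
#' as reference so the printed `centre2`/`centre3`/`centre4` coefficients
#' apply directly.
#'
#' @param data Data frame containing the covariate columns.
#' @param covariates Character vector of covariate column names to include
#'   (default: all covariates in `specs`).
#' @param specs Spec catalogue, see [uk700_specs()].
#' @return Numeric matrix with an `(Intercept)` column and named term columns.
#' @export
design_matrix <- function(data, covariates = model_covariates(specs),
                          specs = uk700_specs()) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  for (v in covariates) {
    sp <- specs[[v]]
    if (is.null(sp)) stop("no variable spec for term '", v, "'")
    if (!v %in% names(data)) stop("missing covariate '", v, "' in data")
    x <- data[[v]]
    if (sp$dtype == "categorical") {
      f <- factor(x, levels = sp$levels)
      if (anyNA(f)) stop("column '", v, "' has values outside its levels or NA")
      for (lev in sp$levels[-1L]) {
        cols[[paste0(v, lev)]] <- as.numeric(f == lev)
      }
    } else {
      cols[[term_names(sp)]] <- transform_fn(sp$transform)(x)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

#' Deterministic sub-seed derivation
#'
#' Mixes a master seed and a stream index through two rounds of a
#' multiplicative congruential map modulo the Mersenne prime 2^31 - 1, so
#' every chain, replicate and stage gets an independent reproducible seed
#' that stays inside R's 32-bit integer range.
#'
#' @param seed Master seed (integer).
#' @param k Stream index (integer >= 1).
#' @return A positive integer seed < 2^31.
#' @export
derive_seed <- function(seed, k) {
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m) + 1
  x <- (x * 48271 + as.double(k) * 30269) %% m
  x <- (x * 69621 + 7) %% m
  as.integer(x) + 1L
}

#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Inverse logit
#' @param x Numeric vector of linear predictors.
#' @return Probabilities.
#' @export
expit <- function(x) stats::plogis(x)
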