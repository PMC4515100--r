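# Shared fixture builders; everything is generated in code at test time.

# small complete dataset with a simulated linear outcome
make_linear_data <- function(n = 200, model = "linear", seed = 42) {
  covs <- generate_covariates(n, correlation = 0.2, seed = seed)
  simulate_outcome(covs, builtin_model(model), seed = seed + 1L)
}

# missing-data object with MCAR missingness in cprs0 only
make_mcar_cprs0 <- function(n = 200, rate = 0.3, seed = 42,
                            model = "linear") {
  full <- make_linear_data(n, model, seed)
  apply_independent_mcar(full, c(cprs0 = rate), seed = seed + 2L)
}

# O(n^2) pair-count AUROC oracle (concordant + half ties)
auroc_bruteforce <- function(y, score) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
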