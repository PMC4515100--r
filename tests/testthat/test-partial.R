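test_that("pattern enumeration recovers the observed covariate subsets", {
  full <- make_linear_data(400, seed = 121)
  md <- apply_independent_mcar(full, c(onset = 0.3, distot = 0.3),
                               seed = 122)
  pats <- enumerate_patterns(md)
  covs <- intersect(model_covariates(), names(full))
  base <- setdiff(covs, c("onset", "distot"))
  # onset/distot each missing independently in ~30% of 400 rows: all four
  # combinations occur
  expect_equal(length(pats), 4L)
  expect_equal(pats[[1]], covs)  # full set sorts first
  expect_true(any(vapply(pats, function(p) setequal(p, base), TRUE)))
  # no missing data: the single full pattern
  md0 <- missing_data(full, matrix(FALSE, nrow(full), ncol(full)))
  expect_equal(enumerate_patterns(md0), stats::setNames(list(covs),
               paste(covs, collapse = "+")))
})

test_that("the canonical monotone design yields the nested pattern ladder", {
  full <- make_linear_data(708, seed = 123)
  md <- apply_staged_mar(full, mar_stages("30"), seed = 124)
  pats <- enumerate_patterns(md)
  expect_equal(lengths(pats), c(7L, 6L, 5L, 4L), ignore_attr = TRUE)
  expect_true(all(c("age", "sex", "status", "centre") %in% pats[[4]]))
})

test_that("pattern models refit the reduced formula on the same stack", {
  md <- make_mcar_cprs0(n = 250, rate = 0.3, seed = 125)
  prim <- impute_chained(md, M = 2, iterations = 3, seed = 126)
  pats <- enumerate_patterns(md)
  pm <- fit_pattern_models(prim, pats, "identity")
  # the full pattern's model equals the full model fit
  cs_full <- fit_per_imputation(prim, link = "identity")
  expect_equal(pm$models[[1]]$coef, cs_full$coef)
  # each partial model's per-imputation coefficients equal a direct fit of
  # that reduced covariate set to the same imputed dataset
  reduced <- pats[[2]]
  direct <- fit_per_imputation(prim$datasets[[2]], covariates = reduced,
                               link = "identity")
  expect_equal(pm$models[[2]]$coef[2, ], direct$coef[1, ])
  # only the primary stack is admissible
  sec <- impute_chained(md, M = 2, iterations = 3, include_outcome = FALSE,
                        seed = 127)
  expect_error(fit_pattern_models(sec, pats, "identity"), "primary")
})

test_that("routing uses observed covariates only", {
  md <- make_mcar_cprs0(n = 250, rate = 0.3, seed = 128)
  prim <- impute_chained(md, M = 3, iterations = 3, seed = 129)
  pats <- enumerate_patterns(md)
  pm <- fit_pattern_models(prim, pats, "identity")
  pp <- predict_partial(pm, md)
  expect_equal(nrow(pp$values), 250L)
  expect_false(anyNA(pp$values))

  # fully observed rows get the full model's P1 prediction
  cs_full <- fit_per_imputation(prim, link = "identity")
  p1 <- predict_per_imputation(cs_full, md)
  cc <- complete_rows(md)
  expect_equal(pp$values[cc, ], p1$values)

  # a row with missing cprs0 routes to the reduced model: hand dot product
  mis_row <- which(md$mask[, "cprs0"])[1]
  id <- md$pattern_id[mis_row]
  cs_red <- pm$models[[id]]
  X <- design_matrix(md$data[mis_row, , drop = FALSE], cs_red$covariates)
  expect_equal(pp$values[mis_row, 2], drop(X %*% cs_red$coef[2, ]))

  # poisoning masked cells must not change any prediction
  md2 <- md
  md2$data$cprs0[md$mask[, "cprs0"]] <- 9e9
  expect_equal(predict_partial(pm, md2)$values, pp$values)

  # pooled coefficients give a single column
  expect_equal(ncol(predict_partial(pm, md, "pooled")$values), 1L)
})

test_that("an unseen pattern at prediction time raises a routing error", {
  md <- make_mcar_cprs0(n = 200, rate = 0.3, seed = 131)
  prim <- impute_chained(md, M = 2, iterations = 3, seed = 132)
  pats <- enumerate_patterns(md)
  pm <- fit_pattern_models(prim, pats, "identity")
  full2 <- make_linear_data(60, seed = 133)
  md2 <- apply_independent_mcar(full2, c(onset = 0.4), seed = 134)
  expect_error(predict_partial(pm, md2), "pattern")
})

test_that("pragmatic partial-model MSPE exceeds ideal MSPE under missingness", {
  reps <- 40
  d_part <- numeric(reps)
  for (r in seq_len(reps)) {
    full <- make_linear_data(300, seed = 5000 + r)
    md <- apply_staged_mar(full, mar_stages("30"), seed = 6000 + r)
    prim <- impute_chained(md, M = 3, iterations = 4, seed = 7000 + r)
    cs <- fit_per_imputation(prim, link = "identity")
    p4 <- predict_per_imputation(cs, prim)
    pm <- fit_pattern_models(prim, enumerate_patterns(md), "identity")
    pp <- predict_partial(pm, md)
    ideal <- pool_performance(full$y, p4, "mspe")$estimate
    pragmatic <- pool_performance(full$y, pp, "mspe")$estimate
    d_part[r] <- pragmatic - ideal
  }
  expect_lt(t.test(d_part, alternative = "greater")$p.value, 0.01)
})
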