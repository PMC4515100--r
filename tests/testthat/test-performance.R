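test_that("MSPE matches hand arithmetic", {
  expect_equal(mspe(c(1, 0), c(0.5, 0.5))$estimate, 0.25)
  expect_equal(mspe(c(0, 2), c(1, 1))$estimate, 1.0)
  y <- rnorm(20)
  expect_equal(mspe(y, y)$estimate, 0)
  expect_error(mspe(numeric(0), numeric(0)), "empty")
})

test_that("AUROC handles separation, constancy and the 4-pair example", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$estimate, 1)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.4, 4))$estimate, 0.5)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))$estimate, 0.75)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "degenerate")
})

test_that("AUROC equals the brute-force pair-count oracle, ties included", {
  set.seed(101)
  for (r in 1:30) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    score <- sample(round(rnorm(n), 1))  # coarse scores force ties
    expect_equal(auroc(y, score)$estimate, auroc_bruteforce(y, score))
  }
})

test_that("AUROC is invariant to strictly monotone score transforms", {
  set.seed(102)
  y <- rbinom(80, 1, 0.3)
  y[1:2] <- c(0, 1)
  lp <- rnorm(80)
  expect_equal(auroc(y, lp)$estimate, auroc(y, plogis(lp))$estimate)
  expect_equal(auroc(y, lp)$estimate, auroc(y, 3 * lp - 7)$estimate)
})

test_that("calibration slope recovers closed-form values", {
  # least-squares fitted values regressed on themselves: slope exactly 1
  full <- make_linear_data(150, seed = 103)
  cs <- fit_per_imputation(full, link = "identity")
  X <- design_matrix(full, cs$covariates)
  fitted <- drop(X %*% cs$coef[1, ])
  expect_equal(calibration_slope(full$y, fitted)$estimate, 1, tolerance = 1e-10)
  # two-point closed form: slope = cov(y, pred) / var(pred) = 1 / 0.5
  expect_equal(calibration_slope(c(0, 2), c(1, 2))$estimate, 2)
  expect_equal(calibration_slope(full$y, full$y)$estimate, 1, tolerance = 1e-12)
  expect_error(calibration_slope(c(0, 1), c(1, 1)), "constant")
})

test_that("pooled performance applies Rubin's rules to replicate measures", {
  pl_y <- rnorm(60)
  set.seed(104)
  vals <- matrix(pl_y + rnorm(60 * 5, sd = 0.4), 60, 5)
  ps <- miperform:::prediction_set(vals, "P4", "imputation_specific",
                                   1:60, "identity")
  pp <- pool_performance(pl_y, ps, "mspe")
  per_rep <- apply(vals, 2, function(v) mspe(pl_y, v))
  ests <- vapply(per_rep, `[[`, 0, "estimate")
  vars <- vapply(per_rep, `[[`, 0, "variance")
  expect_equal(pp$estimate, mean(ests))
  expect_equal(pp$W, mean(vars))
  expect_equal(pp$B, var(ests))
  expect_equal(pp$T, mean(vars) + (1 + 1 / 5) * var(ests))
  expect_identical(pp$strategy, "pooled_performance")

  # identical replicates: no between-imputation variance
  ps2 <- miperform:::prediction_set(vals[, c(1, 1, 1)], "P4",
                                    "imputation_specific", 1:60, "identity")
  expect_equal(pool_performance(pl_y, ps2, "mspe")$B, 0)
})

test_that("pooled-prediction MSPE never exceeds mean replicate MSPE", {
  set.seed(105)
  for (r in 1:50) {
    n <- sample(5:40, 1)
    R <- sample(2:6, 1)
    y <- rnorm(n)
    vals <- matrix(rnorm(n * R), n, R)
    ps <- miperform:::prediction_set(vals, "P4", "imputation_specific",
                                     seq_len(n), "identity")
    pooled <- pool_on_response_scale(ps)
    lhs <- evaluate_pooled_prediction(y, pooled, "mspe")$estimate
    rhs <- pool_performance(y, ps, "mspe")$estimate
    expect_lte(lhs, rhs + 1e-12)
  }
})

test_that("degenerate pooling: M = 1 strategies coincide", {
  full <- make_linear_data(120, seed = 106)
  mask <- matrix(FALSE, nrow(full), ncol(full))
  stack <- impute_chained(missing_data(full, mask), M = 1, seed = 107)
  cs <- fit_per_imputation(stack, link = "identity")
  p4 <- predict_per_imputation(cs, stack)
  pooled <- miperform:::prediction_set(p4$lp, "P5", "imputation_specific",
                                       p4$rows, "identity")
  a <- pool_performance(full$y, p4, "mspe")$estimate
  b <- evaluate_pooled_prediction(full$y, pooled, "mspe")$estimate
  expect_equal(a, b)
})

test_that("logit-transformed AUROC pooling back-transforms the point", {
  set.seed(108)
  y <- rbinom(100, 1, 0.3)
  y[1:2] <- c(0, 1)
  lp <- matrix(y + rnorm(300, sd = 1.2), 100, 3)
  ps <- miperform:::prediction_set(lp, "P4", "imputation_specific",
                                   1:100, "logit")
  raw <- pool_performance(y, ps, "auroc", transform = "none")
  tr <- pool_performance(y, ps, "auroc", transform = "logit")
  per <- apply(ps$values, 2, function(v) auroc(y, v)$estimate)
  expect_equal(raw$estimate, mean(per))
  expect_equal(tr$estimate, plogis(mean(qlogis(per))))
})

test_that("within-imputation calibration of own-coefficient predictions is exact", {
  # each imputed dataset's own fitted values are a least-squares projection,
  # so every within-imputation slope -- and the pooled slope -- is exactly 1
  md <- make_mcar_cprs0(n = 200, rate = 0.3, seed = 109)
  prim <- impute_chained(md, M = 5, iterations = 4, seed = 110)
  cs <- fit_per_imputation(prim, link = "identity")
  p4 <- predict_per_imputation(cs, prim)
  y <- md$data$y
  for (k in 1:5) {
    expect_equal(calibration_slope(y, p4$values[, k])$estimate, 1,
                 tolerance = 1e-10)
  }
  pooled_slope <- pool_performance(y, p4, "calibration_slope")
  expect_equal(pooled_slope$estimate, 1, tolerance = 1e-10)
})

test_that("pooled predictions overstate calibration among imputed rows", {
  # averaging imputations that saw the outcome yields too-steep predictions
  # among the imputed individuals: slope(P5) exceeds the pooled slope there
  md <- make_mcar_cprs0(n = 500, rate = 0.35, seed = 111,
                        model = "linear_strong")
  prim <- impute_chained(md, M = 5, iterations = 5, seed = 112)
  cs <- fit_per_imputation(prim, link = "identity")
  p4 <- predict_per_imputation(cs, prim)
  p5 <- pool_on_response_scale(p4)
  imp_rows <- which(md$mask[, "cprs0"])
  y_imp <- md$data$y[imp_rows]
  slope_p5 <- calibration_slope(y_imp, p5$values[imp_rows, 1])$estimate
  slopes_k <- vapply(1:5, function(k) {
    calibration_slope(y_imp, p4$values[imp_rows, k])$estimate
  }, 0)
  expect_gt(slope_p5, mean(slopes_k))
})
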