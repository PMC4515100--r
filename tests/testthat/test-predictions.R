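# pipeline fixture shared by the prediction-construction tests
local_pipeline <- function(model = "linear", n = 250, seed = 41,
                           M = 3, link = NULL) {
  full <- make_linear_data(n, model, seed)
  md <- apply_independent_mcar(full, c(cprs0 = 0.3, onset = 0.1),
                               seed = seed + 1)
  prim <- impute_chained(md, M = M, iterations = 4, seed = seed + 2)
  sec <- impute_chained(md, M = M, iterations = 4, include_outcome = FALSE,
                        seed = seed + 3)
  if (is.null(link)) link <- if (startsWith(model, "linear")) "identity"
                             else "logit"
  cs <- fit_per_imputation(prim, link = link)
  list(full = full, md = md, prim = prim, sec = sec, cs = cs)
}

test_that("P4 with a single imputation equals the regression's fitted values", {
  d <- make_linear_data(100, seed = 51)
  mask <- matrix(FALSE, nrow(d), ncol(d))
  md <- missing_data(d, mask)
  stack <- impute_chained(md, M = 1, seed = 52)
  cs <- fit_per_imputation(stack, link = "identity")
  p4 <- predict_per_imputation(cs, stack)
  X <- design_matrix(d, cs$covariates)
  expect_equal(p4$values[, 1], drop(X %*% cs$coef[1, ]))
  expect_identical(p4$label, "P4")
})

test_that("replicate predictions evaluate the inverse link exactly", {
  pl <- local_pipeline("logistic_25", seed = 61)
  p4 <- predict_per_imputation(pl$cs, pl$prim)
  for (k in 1:3) {
    X <- design_matrix(pl$prim$datasets[[k]], pl$cs$covariates)
    lp <- drop(X %*% pl$cs$coef[k, ])
    expect_equal(p4$lp[, k], lp)
    expect_equal(p4$values[, k], plogis(lp))
  }
  # frozen spot values: expit(0) and expit(2)
  expect_equal(plogis(c(0, 2)), c(0.5, 0.880797), tolerance = 1e-6)
})

test_that("pooling on the two scales matches direct arithmetic", {
  ps <- miperform:::prediction_set(matrix(c(0, 2), 1, 2), "P4",
                                   "imputation_specific", 1L, "logit")
  expect_equal(ps$values[1, ], c(0.5, 0.8807971), tolerance = 1e-7)
  p5 <- pool_on_response_scale(ps)
  expect_equal(p5$values[1, 1], mean(c(0.5, 0.8807971)), tolerance = 1e-7)
  expect_identical(p5$label, "P5")
  p6 <- pool_on_linear_scale(ps)
  expect_equal(p6$values[1, 1], plogis(1), tolerance = 1e-12)
  expect_identical(p6$label, "P6")
  # identical replicates pool to themselves
  ps2 <- miperform:::prediction_set(matrix(0.3, 2, 3), "P1",
                                    "imputation_specific", 1:2, "identity")
  expect_equal(pool_on_response_scale(ps2)$values[, 1], c(0.3, 0.3))
  expect_error(pool_on_response_scale(pool_on_response_scale(ps)),
               "already pooled")
})

test_that("identity link makes response- and linear-scale pooling equal", {
  pl <- local_pipeline("linear", seed = 71)
  for (src in list(pl$md, pl$prim, pl$sec)) {
    p <- predict_per_imputation(pl$cs, src)
    a <- pool_on_response_scale(p)
    b <- pool_on_linear_scale(p)
    expect_lt(max(abs(a$values - b$values)), 1e-12)
  }
})

test_that("P7 reduces to P1 for fully observed individuals", {
  pl <- local_pipeline("linear", seed = 81)
  p1 <- predict_per_imputation(pl$cs, pl$md)
  p7 <- predict_per_imputation(pl$cs, pl$sec)
  cc <- complete_rows(pl$md)
  expect_identical(p1$rows, cc)
  # under the full (j,k) grid, the column with coefficient k at a complete
  # case equals that case's P1 value for k
  for (k in 1:3) {
    cols <- which(p7$replicate_index$k == k)
    for (j in cols) {
      expect_equal(p7$values[cc, j], p1$values[, k])
    }
  }
  # P4 = P1 on complete cases, hence P5 = P2 and P6 = P3 there
  p4 <- predict_per_imputation(pl$cs, pl$prim)
  expect_equal(p4$values[cc, ], p1$values)
  expect_equal(pool_on_response_scale(p4)$values[cc, 1],
               pool_on_response_scale(p1)$values[, 1])
})

test_that("P7 grid shape and provenance contracts are enforced", {
  pl <- local_pipeline("linear", seed = 91)
  p7 <- predict_per_imputation(pl$cs, pl$sec)
  expect_equal(ncol(p7$values), 9L)  # M2 x M grid
  p7p <- predict_per_imputation(pl$cs, pl$sec, coef_mode = "pooled")
  expect_equal(ncol(p7p$values), 3L)  # M2 columns under pooled coefficients
  p7pair <- predict_per_imputation(pl$cs, pl$sec, grid = "paired")
  expect_equal(ncol(p7pair$values), 3L)
  expect_error(predict_per_imputation(pl$cs, pl$prim, grid = "full"), NA)
  # a primary (outcome-included) stack cannot stand in for the second
  # imputation procedure
  prim2 <- pl$prim
  prim2$provenance <- "secondary"
  expect_error(predict_per_imputation(pl$cs, prim2), "contract")
})

test_that("rank order is preserved by linear-scale pooling under logit", {
  pl <- local_pipeline("logistic_25", seed = 95)
  p4 <- predict_per_imputation(pl$cs, pl$prim)
  p6 <- pool_on_linear_scale(p4)
  expect_equal(rank(p6$values[, 1]), rank(rowMeans(p4$lp)))
  # Jensen gap vanishes only when replicate linear predictors agree
  p5 <- pool_on_response_scale(p4)
  expect_gt(max(abs(p5$values - p6$values)), 0)
})
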