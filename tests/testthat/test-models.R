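test_that("metrics match their closed forms on hand-computable vectors", {
  expect_equal(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r2(c(1, 2, 3), c(2, 2, 2)), 0)     # mean predictor
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
  expect_equal(mae(c(0, 0), c(1, -1)), 1)
  expect_error(r2(c(2, 2), c(1, 3)), "constant")
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("rmse dominates mae and r2 is affine-invariant", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    y <- rnorm(n); yh <- rnorm(n)
    expect_gte(rmse(y, yh), mae(y, yh))
    expect_gte(mae(y, yh), 0)
    if (sd(y) > 0) {
      a <- runif(1, 0.5, 3); b <- rnorm(1)
      expect_equal(r2(a * y + b, a * yh + b), r2(y, yh), tolerance = 1e-10)
    }
  }
})

test_that("qualitative grades follow the published bands", {
  expect_equal(grade(0.97), "excellent")
  expect_equal(grade(0.83), "good")
  expect_equal(grade(0.49), "not-quantifiable")
  expect_equal(grade(0.9), "good")                # boundary resolves down
  expect_equal(grade(0.82), "good")
  expect_equal(grade(0.66), "approximate-quantitative")
  expect_equal(grade(0.5), "feasible-needs-improvement")
  expect_error(grade(1.2), "exceed")
  # monotone step function
  v <- sort(runif(100, -1, 1))
  lv <- c("not-quantifiable", "feasible-needs-improvement",
          "approximate-quantitative", "good", "excellent")
  expect_false(is.unsorted(match(grade(v), lv)))
})

test_that("model specs validate names and hyperparameter keys", {
  expect_error(modelSpec("OLS"), "arg")
  expect_error(modelSpec("SVMR", params = list(bogus = 1)), "bogus")
  expect_length(defaultModelSpecs(), 7L)
  expect_named(defaultModelSpecs(),
               c("PLSR", "BRR", "RR", "KRR", "SVMR", "XGBoost", "RFR"))
})

test_that("linear-identifiable data is reproduced by the linear models", {
  set.seed(24)
  x <- rnorm(40)
  y <- 1.7 * x + 4
  Xc <- matrix(x[1:30]); Xv <- matrix(x[31:40])
  sc <- standardize(Xc, Xv)
  for (nm in c("PLSR", "RR")) {
    pred <- fitPredict(modelSpec(nm), sc$train, y[1:30], sc$test)
    expect_equal(pred, y[31:40], tolerance = 1e-6)
  }
  predB <- fitPredict(modelSpec("BRR"), sc$train, y[1:30], sc$test)
  expect_equal(predB, y[31:40], tolerance = 1e-4)
})

test_that("stochastic models are deterministic given the seed", {
  set.seed(25)
  X <- matrix(rnorm(120), 30)
  y <- drop(X %*% c(1, 0.5, -0.5, 0)) + rnorm(30, 0, 0.2)
  sc <- standardize(X[1:22, ], X[23:30, ])
  for (nm in c("XGBoost", "RFR", "SVMR", "KRR")) {
    p1 <- fitPredict(modelSpec(nm, seed = 7), sc$train, y[1:22], sc$test)
    p2 <- fitPredict(modelSpec(nm, seed = 7), sc$train, y[1:22], sc$test)
    expect_identical(p1, p2)
    expect_true(all(is.finite(p1)))
  }
})

test_that("random forest beats the mean predictor on a learnable signal", {
  set.seed(26)
  x <- seq(-2, 2, length.out = 10)
  y <- 2 * x + rnorm(10, 0, 0.1)
  xv <- seq(-1.8, 1.8, length.out = 6)
  yv <- 2 * xv
  sc <- standardize(matrix(x), matrix(xv))
  pred <- fitPredict(modelSpec("RFR", seed = 5), sc$train, y, sc$test)
  expect_lte(rmse(yv, pred), rmse(yv, rep(mean(y), 6)))
})

test_that("the benchmark grid is complete and flags the best model", {
  set.seed(27)
  n <- 30
  z <- rnorm(n)
  y <- 9 + z
  reg <- list(A = cbind(-z + rnorm(n, 0, 0.2), z + rnorm(n, 0, 0.3)),
              B = cbind(z + rnorm(n, 0, 0.05)))
  sp <- spxySplit(reg$A, y, 20)
  rep1 <- benchmark(reg, y, sp)
  expect_equal(nrow(rep1), 14L)
  expect_equal(sum(rep1$best), 2L)
  for (rg in c("A", "B")) {
    sub <- rep1[rep1$regime == rg, ]
    ord <- order(-sub$Rp2, sub$RMSEp)
    expect_true(sub$best[ord[1]])
  }
  expect_true(all(rep1$RMSEp >= rep1$MAEp, na.rm = TRUE))
})

test_that("an all-noise target grades as not-quantifiable", {
  set.seed(28)
  n <- 40
  X <- matrix(rnorm(n * 3), n)
  y <- rnorm(n) + 9
  sp <- spxySplit(X, y, 27)
  rep1 <- benchmark(list(noise = X), y, sp)
  expect_true(all(rep1$grade == "not-quantifiable", na.rm = TRUE))
})

test_that("a single failing model is recorded without breaking the grid", {
  set.seed(29)
  X <- matrix(rnorm(60), 20)
  y <- rnorm(20) + 9
  sp <- spxySplit(X, y, 14)
  specs <- list(SVMR = modelSpec("SVMR", params = list(cost = -1)),
                PLSR = modelSpec("PLSR"))
  rep1 <- benchmark(list(X = X), y, sp, specs)
  expect_equal(nrow(rep1), 2L)
  bad <- rep1[rep1$model == "SVMR", ]
  expect_false(is.na(bad$error))
  expect_true(is.na(bad$Rp2))
  good <- rep1[rep1$model == "PLSR", ]
  expect_true(is.na(good$error))
  expect_false(is.na(good$Rp2))
})
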