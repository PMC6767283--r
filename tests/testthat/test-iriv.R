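test_that("design matrix is balanced, deterministic and complement-stable", {
  A <- generateDesignMatrix(7, 10, seed = 4)
  expect_equal(dim(A), c(10L, 7L))
  expect_true(all(colSums(A) == 5))
  expect_identical(A, generateDesignMatrix(7, 10, seed = 4))
  expect_false(identical(A, generateDesignMatrix(7, 10, seed = 5)))
  B3 <- A; B3[, 3] <- 1L - B3[, 3]          # complement of a balanced column
  expect_equal(colSums(B3)[3], c(5))
  expect_error(generateDesignMatrix(4, 7, seed = 1), "even")
})

test_that("config validation rejects impossible settings", {
  expect_error(irivConfig(nRows = 3), "even")
  expect_error(irivConfig(cvFolds = 1), "at least 2")
  expect_error(irivConfig(alpha = 1.2), "\\(0, 1\\)")
  expect_error(irivConfig(maxPlsFactors = 0), "at least 1")
})

test_that("RMSECV is near zero for a perfect fit and +Inf for no variables", {
  set.seed(1)
  x <- rnorm(40)
  y <- 3 * x + 1
  expect_lt(rmsecv(matrix(x), y, irivConfig(seed = 2)), 1e-8)
  expect_identical(rmsecv(matrix(numeric(0), 40, 0), y), Inf)
  cfg <- irivConfig(seed = 9)
  X <- matrix(rnorm(80), 40, 2)
  expect_identical(rmsecv(X, y, cfg), rmsecv(X, y, cfg))
})

test_that("RMSECV on an irrelevant predictor tracks the mean-predictor error", {
  set.seed(5)
  x <- rnorm(60)
  y <- rnorm(60)
  cfg <- irivConfig(seed = 5)
  folds <- irivsca:::makeFolds(60, 5, 5)
  got <- rmsecv(matrix(x), y, cfg, folds)
  # oracle: fold-wise mean predictor, pooled over the same partition
  sse <- 0
  for (k in 1:5) {
    m <- mean(y[folds != k])
    sse <- sse + sum((y[folds == k] - m)^2)
  }
  oracle <- sqrt(sse / 60)
  expect_gt(got, 0.7 * oracle)
  expect_lt(got, 1.1 * oracle)
})

test_that("scoring separates a sole predictor from noise", {
  set.seed(11)
  n <- 50
  x1 <- rnorm(n)
  X <- cbind(x1, matrix(rnorm(n * 5), n))
  y <- 2 * x1 + rnorm(n, 0, 0.3)
  cfg <- irivConfig(nRows = 100, seed = 11)
  A <- generateDesignMatrix(6, 100, 11)
  sc <- scoreVariables(X, y, A, cfg)
  expect_lt(sc$dmean[1], 0)
  expect_lt(sc$p[1], 0.05)
})

test_that("a pure-noise variable among strong predictors is never retained", {
  for (s in 1:5) {
    set.seed(s)
    n <- 50
    Xs <- matrix(rnorm(n * 3), n)
    y <- drop(Xs %*% c(2, 1.5, 1)) + rnorm(n, 0, 0.3)
    X <- cbind(Xs, noise = rnorm(n))
    cfg <- irivConfig(nRows = 100, seed = s)
    A <- generateDesignMatrix(4, 100, s)
    sc <- scoreVariables(X, y, A, cfg)
    # inclusion of noise raises the error (eliminated), and its effect is
    # an order of magnitude below the real predictor's benefit
    expect_gt(sc$dmean[4], 0)
    expect_lt(abs(sc$dmean[4]), abs(sc$dmean[1]))
  }
})

test_that("identical score pools give DMEAN 0 and p 1", {
  expect_equal(irivsca:::mannWhitneyP(c(1, 2, 3, 4), c(4, 3, 2, 1)), 1)
})

test_that("variable typing reproduces the four-quadrant rule", {
  expect_equal(classifyVariable(-0.3, 0.01), "strong")
  expect_equal(classifyVariable(-0.3, 0.50), "weak")
  expect_equal(classifyVariable(0.2, 0.01), "interfering")
  expect_equal(classifyVariable(0.2, 0.50), "uninformative")
  expect_equal(classifyVariable(0, 0.01), "uninformative")
  expect_error(classifyVariable(0.1, 1.5), "\\[0, 1\\]")
})

test_that("backward elimination drops an exact duplicate column", {
  set.seed(21)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind(x1, x2, x1)                    # column 3 duplicates column 1
  y <- 2 * x1 + x2 + rnorm(n, 0, 0.2)
  be <- backwardEliminate(X, y, 1:3, irivConfig(seed = 21))
  expect_lt(length(be$vars), 3L)
  expect_true(any(c(1, 3) %in% be$vars))    # one copy survives
  expect_true(2 %in% be$vars)
})

test_that("backward elimination keeps a single perfect predictor", {
  set.seed(22)
  x <- rnorm(40)
  be <- backwardEliminate(matrix(x), 2 * x + 5, 1L, irivConfig(seed = 22))
  expect_identical(be$vars, 1L)
  be2 <- backwardEliminate(matrix(x), 2 * x + 5, 1L, irivConfig(seed = 22))
  expect_identical(be, be2)
})

test_that("greedy elimination never beats exhaustive best-subset search", {
  cfg <- irivConfig(seed = 31)
  for (case in 1:3) {
    set.seed(30 + case)
    n <- 30; p <- 8
    X <- matrix(rnorm(n * p), n)
    y <- switch(case,
                drop(X %*% c(2, rep(0, p - 1))) ,           # single carrier
                drop(X %*% c(1.5, -1, 0.8, rep(0, p - 3))) + rnorm(n, 0, 0.4),
                rnorm(n))
    folds <- irivsca:::makeFolds(n, cfg$cvFolds, cfg$seed)
    subsets <- lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
    all_r <- vapply(subsets, function(sbs)
      irivsca:::.cppSubsetRmsecv(X, y, sbs, folds, cfg$maxPlsFactors),
      numeric(1))
    best <- min(all_r)
    be <- backwardEliminate(X, y, seq_len(p), cfg, folds)
    expect_gte(be$rmsecv, best - 1e-10)
    if (case == 1) expect_equal(be$rmsecv, best, tolerance = 1e-6)
  }
})

test_that("IRIV recovers planted bands with monotone round shrinkage", {
  cfg0 <- smallPlantedConfig(seed = 301)
  ss <- simulateSpectra(cfg0)
  res <- runIriv(ss, irivConfig(nRows = 100, seed = 301))
  expect_gte(sum(cfg0$plantedBands %in% finalBands(res)), 3)
  expect_true(all(diff(res@retainedCounts) <= 0))
  expect_true(all(finalBands(res) %in%
                  res@rounds[[length(res@rounds)]]$wavelength))
  # fast early shrinkage: by round 3 less than 30% of the grid survives
  r3 <- min(3, length(res@retainedCounts))
  expect_lt(res@retainedCounts[r3], 0.3 * 40)
})

test_that("the full IRIV run is deterministic given data, config and seed", {
  cfg0 <- smallPlantedConfig(seed = 302, nBands = 25,
                             planted = c(500, 900, 1400))
  ss <- simulateSpectra(cfg0)
  cfg <- irivConfig(nRows = 60, seed = 302)
  r1 <- runIriv(ss, cfg)
  r2 <- runIriv(ss, cfg)
  expect_identical(finalBands(r1), finalBands(r2))
  expect_identical(r1@rounds, r2@rounds)
  expect_identical(r1@finalRmsecv, r2@finalRmsecv)
})

test_that("the SIMPLS kernel agrees with an independent PLS implementation", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(41)
  n <- 25; p <- 6; ncomp <- 3
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p)))
  y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.5)
  Xnew <- matrix(rnorm(5 * p), 5, dimnames = list(NULL, paste0("v", 1:p)))
  fit <- irivsca:::.cppPlsCoef(X, y, ncomp)
  ours <- drop(Xnew %*% fit$beta) + fit$intercept
  mo <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression", scale = FALSE)
  theirs <- unname(drop(predict(mo, Xnew)$predict[, 1, ncomp]))
  expect_equal(ours, theirs, tolerance = 1e-6)
})
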