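#' Accuracy metrics
#'
#' \code{r2()} is the coefficient of determination
#' \eqn{1 - \sum(\hat y - y)^2 / \sum(y - \bar y)^2} (exactly 0 for the
#' mean predictor, negative when worse); \code{rmse()} the root-mean-square
#' error; \code{mae()} the mean absolute error.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return A single numeric value.
#' @examples
#' r2(c(1, 2, 3), c(2, 2, 2))   # 0
#' @export
r2 <- function(y, yhat) {
  checkPair(y, yhat)
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop("R^2 is undefined for a constant observed vector")
  1 - sum((yhat - y)^2) / ss
}

#' @rdname r2
#' @export
rmse <- function(y, yhat) {
  checkPair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname r2
#' @export
mae <- function(y, yhat) {
  checkPair(y, yhat)
  mean(abs(y - yhat))
}

checkPair <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat))
    stop("'y' and 'yhat' must be nonempty and of equal length")
  invisible(TRUE)
}

#' Qualitative grading of a coefficient of determination
#'
#' The conventional soil-spectroscopy bands: above 0.9 the prediction is
#' excellent; in \code{[0.82, 0.9]} good (usable for actual detection); in
#' \code{[0.66, 0.82)} approximate quantitative prediction; in
#' \code{[0.5, 0.66)} feasible but needing improvement; below 0.5 the
#' component is not quantifiable from the spectra.  The printed bands
#' overlap at exactly 0.9 ("good" is \code{<= 0.9}, "excellent"
#' \code{> 0.9}), so 0.9 itself grades as good.
#'
#' @param r2Value numeric vector of R-squared values (each \code{<= 1}).
#' @return Character vector of grades.
#' @examples
#' grade(c(0.97, 0.83, 0.49))
#' @export
grade <- function(r2Value) {
  if (any(r2Value > 1 + 1e-12, na.rm = TRUE))
    stop("R^2 cannot exceed 1")
  ifelse(r2Value > 0.9, "excellent",            # "good" band is closed at 0.9
  ifelse(r2Value >= 0.82, "good",
  ifelse(r2Value >= 0.66, "approximate-quantitative",
  ifelse(r2Value >= 0.5, "feasible-needs-improvement",
         "not-quantifiable"))))
}

#' Model specification for the regression harness
#'
#' The closed set of supported regressors: partial least squares (PLSR,
#' in-package SIMPLS), Bayesian ridge (BRR, evidence maximization), ridge
#' (RR, \code{MASS::lm.ridge}), kernel ridge (KRR, closed-form RBF),
#' support vector machine (SVMR, \code{e1071}), gradient boosting
#' (XGBoost) and random forest (RFR).  Hyperparameters are fixed documented
#' defaults (no tuning is performed); any default can be overridden, and
#' unknown keys are rejected.
#'
#' @param name one of \code{"PLSR"}, \code{"BRR"}, \code{"RR"},
#'   \code{"KRR"}, \code{"SVMR"}, \code{"XGBoost"}, \code{"RFR"}.
#' @param params named list of hyperparameter overrides.
#' @param seed integer seed for the stochastic models (XGBoost, RFR).
#' @return List of class \code{"modelSpec"}.
#' @export
modelSpec <- function(name, params = list(), seed = 1L) {
  name <- match.arg(name, names(modelDefaults))
  defaults <- modelDefaults[[name]]
  bad <- setdiff(names(params), names(defaults))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(bad, collapse = ", "))
  structure(list(name = name,
                 params = modifyList(defaults, params),
                 seed = as.integer(seed)),
            class = "modelSpec")
}

# documented fixed defaults of the harness (see the methods vignette)
modelDefaults <- list(
  PLSR = list(ncomp = 10),
  BRR = list(maxIter = 300, tol = 1e-3,
             alpha1 = 1e-6, alpha2 = 1e-6, lambda1 = 1e-6, lambda2 = 1e-6),
  RR = list(lambda = 1e-6),     # near-OLS default; raise for regularization
  KRR = list(lambda = 1, gamma = NA),       # gamma NA -> 1/ncol(X)
  SVMR = list(cost = 1, epsilon = 0.1, gamma = NA),
  XGBoost = list(nrounds = 200, eta = 0.1, max_depth = 3,
                 subsample = 1, colsample_bytree = 1),
  RFR = list(ntree = 500, mtry = NA)        # mtry NA -> max(p/3, 1)
)

#' The default seven-model roster
#'
#' @param seed seed applied to every spec.
#' @return Named list of [modelSpec()] objects.
#' @export
defaultModelSpecs <- function(seed = 1L) {
  nm <- names(modelDefaults)
  stats::setNames(lapply(nm, modelSpec, seed = seed), nm)
}

#' Fit a model and predict held-out samples
#'
#' Uniform fit/predict surface over the seven regressors.  Inputs are
#' expected to be standardized (see [standardize()]); predictions are
#' returned on the target scale.  Stochastic models are deterministic given
#' the spec's seed.
#'
#' @param spec a [modelSpec()].
#' @param Xc,yc calibration features and target.
#' @param Xv validation features.
#' @return Numeric predictions, one per row of \code{Xv}.
#' @export
fitPredict <- function(spec, Xc, yc, Xv) {
  if (!inherits(spec, "modelSpec")) stop("'spec' must be a modelSpec")
  Xc <- as.matrix(Xc); Xv <- as.matrix(Xv); yc <- as.numeric(yc)
  p <- spec$params
  pred <- withSeed(spec$seed, switch(
    spec$name,
    PLSR = {
      fit <- .cppPlsCoef(Xc, yc, as.integer(min(p$ncomp, ncol(Xc),
                                                nrow(Xc) - 1L)))
      drop(Xv %*% fit$beta) + fit$intercept
    },
    BRR = predictBayesRidge(Xc, yc, Xv, p),
    RR = ridgePredict(Xc, yc, Xv, p$lambda),
    KRR = predictKernelRidge(Xc, yc, Xv, p),
    SVMR = {
      g <- if (is.na(p$gamma)) 1 / ncol(Xc) else p$gamma
      fit <- e1071::svm(Xc, yc, type = "eps-regression", kernel = "radial",
                        cost = p$cost, epsilon = p$epsilon, gamma = g,
                        scale = FALSE)
      as.numeric(predict(fit, Xv))
    },
    XGBoost = {
      fit <- xgboost::xgboost(
        Xc, yc, objective = "reg:squarederror", nrounds = p$nrounds,
        max_depth = p$max_depth, learning_rate = p$eta,
        subsample = p$subsample, colsample_bytree = p$colsample_bytree,
        nthreads = 1, seed = spec$seed, verbosity = 0)
      as.numeric(predict(fit, Xv))
    },
    RFR = {
      m <- if (is.na(p$mtry)) max(floor(ncol(Xc) / 3), 1) else p$mtry
      fit <- randomForest::randomForest(Xc, yc, ntree = p$ntree, mtry = m)
      as.numeric(predict(fit, Xv))
    }))
  if (any(!is.finite(pred)))
    stop("model ", spec$name, " produced non-finite predictions")
  pred
}

# closed-form ridge on centered data: beta = (X'X + lambda I)^-1 X'y
ridgePredict <- function(Xc, yc, Xv, lambda) {
  xm <- colMeans(Xc); ym <- mean(yc)
  X <- sweep(Xc, 2, xm)
  beta <- solve(crossprod(X) + lambda * diag(ncol(X)),
                crossprod(X, yc - ym))
  drop(sweep(Xv, 2, xm) %*% beta) + ym
}

# Bayesian ridge regression via evidence (marginal likelihood) maximization:
# gaussian prior N(0, lambda^-1 I) on weights, noise precision alpha, both
# updated by the MacKay fixed-point rules on the SVD of the centered design.
predictBayesRidge <- function(Xc, yc, Xv, p) {
  n <- nrow(Xc)
  xm <- colMeans(Xc); ym <- mean(yc)
  X <- sweep(Xc, 2, xm); yz <- yc - ym
  sv <- svd(X)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yz)
  alpha <- 1 / max(stats::var(yz), 1e-12)   # noise precision
  lambda <- 1                               # weight precision
  for (it in seq_len(p$maxIter)) {
    gamma <- sum(alpha * d2 / (alpha * d2 + lambda))
    coefS <- alpha * sv$d * uty / (alpha * d2 + lambda)  # rotated weights
    w2 <- sum(coefS^2)
    rss <- sum(yz^2) - 2 * sum(coefS * sv$d * uty) + sum(coefS^2 * d2)
    lambdaNew <- (gamma + 2 * p$lambda1) / (w2 + 2 * p$lambda2)
    alphaNew <- (n - gamma + 2 * p$alpha1) / (max(rss, 1e-12) + 2 * p$alpha2)
    conv <- abs(lambdaNew - lambda) < p$tol * max(1, lambda) &&
      abs(alphaNew - alpha) < p$tol * max(1, alpha)
    lambda <- lambdaNew; alpha <- alphaNew
    if (conv) break
  }
  coefS <- alpha * sv$d * uty / (alpha * d2 + lambda)
  beta <- sv$v %*% coefS
  drop(sweep(Xv, 2, xm) %*% beta) + ym
}

# closed-form kernel ridge with RBF kernel; y centered, no other intercept
predictKernelRidge <- function(Xc, yc, Xv, p) {
  g <- if (is.na(p$gamma)) 1 / ncol(Xc) else p$gamma
  rbf <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    exp(-g * pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0))
  }
  K <- rbf(Xc, Xc)
  ym <- mean(yc)
  dual <- solve(K + p$lambda * diag(nrow(K)), yc - ym)
  drop(rbf(Xv, Xc) %*% dual) + ym
}

#' Benchmark feature regimes across the model roster
#'
#' Fills the full (regime x model) grid: for each feature regime the
#' calibration/validation split is applied, features are standardized on
#' calibration statistics, every model is fitted, and calibration
#' (\code{Rc2/RMSEc/MAEc}) and validation (\code{Rp2/RMSEp/MAEp}) metrics
#' plus the qualitative grade of \code{Rp2} are recorded.  A single model
#' failure is recorded in the \code{error} column, not fatal to the grid.
#' Within each regime the best model is flagged (highest \code{Rp2}, ties
#' to lowest \code{RMSEp}).
#'
#' @param regimes named list of samples-by-features matrices (all samples;
#'   e.g. \code{list(IRIV = ..., `IRIV-SCA` = ...)}).
#' @param y full target vector.
#' @param split a [SplitResult-class] shared by all regimes.
#' @param specs list of [modelSpec()]s, default [defaultModelSpecs()].
#' @return data.frame (the benchmark report) with one row per
#'   (regime, model).
#' @export
benchmark <- function(regimes, y, split, specs = defaultModelSpecs()) {
  stopifnot(is.list(regimes), length(regimes) > 0)
  if (is.null(names(regimes))) names(regimes) <- paste0("regime", seq_along(regimes))
  ci <- calibrationIdx(split); vi <- validationIdx(split)
  rows <- list()
  for (rg in names(regimes)) {
    Xall <- as.matrix(regimes[[rg]])
    if (nrow(Xall) != length(y))
      stop("regime '", rg, "' has ", nrow(Xall), " samples but target has ",
           length(y))
    sc <- standardize(Xall[ci, , drop = FALSE], Xall[vi, , drop = FALSE])
    for (nm in names(specs)) {
      row <- data.frame(regime = rg, model = specs[[nm]]$name,
                        Rc2 = NA_real_, RMSEc = NA_real_, MAEc = NA_real_,
                        Rp2 = NA_real_, RMSEp = NA_real_, MAEp = NA_real_,
                        grade = NA_character_, best = FALSE,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        predC <- fitPredict(specs[[nm]], sc$train, y[ci], sc$train)
        predV <- fitPredict(specs[[nm]], sc$train, y[ci], sc$test)
        list(predC = predC, predV = predV)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$Rc2 <- r2(y[ci], res$predC)
        row$RMSEc <- rmse(y[ci], res$predC)
        row$MAEc <- mae(y[ci], res$predC)
        row$Rp2 <- r2(y[vi], res$predV)
        row$RMSEp <- rmse(y[vi], res$predV)
        row$MAEp <- mae(y[vi], res$predV)
        row$grade <- grade(row$Rp2)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- do.call(rbind, rows)
  for (rg in unique(report$regime)) {
    sel <- which(report$regime == rg & !is.na(report$Rp2))
    if (length(sel)) {
      ord <- sel[order(-report$Rp2[sel], report$RMSEp[sel])]
      report$best[ord[1]] <- TRUE
    }
  }
  report
}
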