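#' IRIV configuration
#'
#' Knobs of the iteratively-retaining-informative-variables selector.  The
#' sub-model count follows the balanced binary-matrix (BMSF-style) design;
#' five-fold cross-validation, a cap of 10 PLS latent factors and the 0.05
#' Mann-Whitney threshold are the conventional settings for this selector.
#'
#' @param nRows number of randomized sub-models (rows of the binary design
#'   matrix); must be even, default 500.
#' @param cvFolds cross-validation folds, default 5.
#' @param maxPlsFactors cap on PLS latent factors, default 10; each sub-model
#'   uses \code{min(maxPlsFactors, n_included, n_train - 1)}.
#' @param alpha Mann-Whitney significance threshold, default 0.05.
#' @param seed integer RNG seed driving the design matrices and the fold
#'   partition.
#' @param maxRounds safety cap on elimination rounds, default 20.
#' @return A validated list of class \code{"irivConfig"}.
#' @export
irivConfig <- function(nRows = 500L, cvFolds = 5L, maxPlsFactors = 10L,
                       alpha = 0.05, seed = 1L, maxRounds = 20L) {
  nRows <- as.integer(nRows)
  if (nRows < 2L || nRows %% 2L != 0L)
    stop("'nRows' must be an even integer >= 2")
  if (cvFolds < 2L) stop("'cvFolds' must be at least 2")
  if (maxPlsFactors < 1L) stop("'maxPlsFactors' must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  structure(list(nRows = nRows, cvFolds = as.integer(cvFolds),
                 maxPlsFactors = as.integer(maxPlsFactors),
                 alpha = alpha, seed = as.integer(seed),
                 maxRounds = as.integer(maxRounds)),
            class = "irivConfig")
}

# internal: evaluate expr under a temporary RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Balanced binary design matrix for IRIV sub-models
#'
#' Each column holds exactly \code{nRows/2} ones and \code{nRows/2} zeros in
#' an independently permuted order, so every variable is included in exactly
#' half of the sub-models and the complemented matrix B (used for the
#' exclusion sub-models) is balanced too.
#'
#' @param p number of variables (columns).
#' @param nRows number of sub-models; must be even.
#' @param seed integer seed; the matrix is deterministic given
#'   \code{(p, nRows, seed)}.
#' @return Integer 0/1 matrix of dimension \code{nRows x p}.
#' @export
generateDesignMatrix <- function(p, nRows, seed) {
  nRows <- as.integer(nRows)
  if (nRows %% 2L != 0L) stop("'nRows' must be even")
  withSeed(seed, {
    vapply(seq_len(p),
           function(j) sample(rep(c(0L, 1L), each = nRows %/% 2L)),
           integer(nRows))
  })
}

# internal: balanced fold labels 1..k, fixed for a whole IRIV run
makeFolds <- function(n, k, seed) {
  if (k > n) stop("more folds (", k, ") than samples (", n, ")")
  withSeed(seed, sample(rep_len(seq_len(k), n)))
}

#' Cross-validated PLS error of a variable subset
#'
#' Pooled k-fold root-mean-square error of cross-validation (RMSECV) of a
#' PLS regression on the given columns, the scoring criterion of IRIV.  An
#' empty subset cannot predict and scores \code{+Inf}.
#'
#' @param X numeric samples-by-variables matrix.
#' @param y numeric target.
#' @param cfg an [irivConfig()].
#' @param folds optional fold labels (1..k) to reuse across calls; defaults
#'   to a seeded partition from \code{cfg}.
#' @return Non-negative scalar (possibly \code{Inf}).
#' @export
rmsecv <- function(X, y, cfg = irivConfig(), folds = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) return(Inf)
  if (is.null(folds)) folds <- makeFolds(nrow(X), cfg$cvFolds, cfg$seed)
  .cppSubsetRmsecv(X, as.numeric(y), seq_len(ncol(X)), as.integer(folds),
                   cfg$maxPlsFactors)
}

#' Score every variable by inclusion/exclusion sub-models
#'
#' For the design matrix A, the RMSECV of each row's sub-model is computed
#' (vector RMSECV0); for every variable i the i-th column is complemented
#' (matrix B) and each row re-scored (RMSECVi).  The inclusion pool
#' \eqn{\phi_0} collects the scores of sub-models that contain variable i
#' (rows of A with \eqn{A_{ki}=1} and rows of B with \eqn{B_{ki}=1});
#' \eqn{\phi_i} collects those that exclude it.  \code{DMEAN_i} is
#' \code{mean(phi0) - mean(phi_i)} (negative means inclusion lowers the
#' error, i.e. the variable is informative) and \code{p_i} is the two-sided
#' Mann-Whitney U p-value between the two pools.  Sub-models containing no
#' variables at all score \code{+Inf} and are dropped from both pools.
#'
#' @param X samples-by-variables matrix.
#' @param y numeric target.
#' @param A balanced binary design matrix from [generateDesignMatrix()].
#' @param cfg an [irivConfig()].
#' @param folds optional fixed fold labels.
#' @return data.frame with columns \code{dmean} and \code{p}, one row per
#'   variable.
#' @export
scoreVariables <- function(X, y, A, cfg = irivConfig(), folds = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(folds)) folds <- makeFolds(nrow(X), cfg$cvFolds, cfg$seed)
  res <- .cppScoreAll(X, y, A, as.integer(folds), cfg$maxPlsFactors)
  r0 <- drop(res$rmsecv0)
  ri <- res$rmsecvi
  p <- ncol(A)
  dmean <- numeric(p)
  pval <- numeric(p)
  for (i in seq_len(p)) {
    inA <- A[, i] == 1L
    phi0 <- c(r0[inA], ri[!inA, i])    # B_ki = 1 - A_ki
    phii <- c(r0[!inA], ri[inA, i])
    phi0 <- phi0[is.finite(phi0)]      # empty sub-models score +Inf; drop
    phii <- phii[is.finite(phii)]
    if (length(phii) == 0L) {          # exclusion impossible (p = 1):
      dmean[i] <- -Inf                 # a model always beats no model
      pval[i] <- 0
    } else if (length(phi0) == 0L) {
      dmean[i] <- Inf
      pval[i] <- 0
    } else {
      dmean[i] <- mean(phi0) - mean(phii)
      pval[i] <- mannWhitneyP(phi0, phii)
    }
  }
  # differences within floating-point noise of zero carry no evidence;
  # snap them to 0 so inert variables type as uninformative
  scale <- mean(abs(c(r0[is.finite(r0)], 1e-300)))
  dmean[abs(dmean) < 1e-9 * max(scale, 1e-12)] <- 0
  data.frame(dmean = dmean, p = pval)
}

# internal: two-sided Mann-Whitney U; exact for small tie-free pools,
# normal approximation with tie/continuity correction otherwise
mannWhitneyP <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  # identical pools sit exactly at the null center of U; report p = 1
  # directly instead of the continuity-corrected approximation's ~0.99
  if (length(a) == length(b) && identical(sort(a), sort(b))) return(1)
  exact <- min(length(a), length(b)) < 8 && !anyDuplicated(c(a, b))
  suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Four-quadrant IRIV variable typing
#'
#' Applies the sign-of-DMEAN by Mann-Whitney-significance rule: negative
#' DMEAN means the variable lowers the cross-validated error when included
#' (\code{"strong"} if significant at \code{alpha}, else \code{"weak"});
#' positive DMEAN means it raises the error (\code{"interfering"} if
#' significant, else \code{"uninformative"}).  A DMEAN of exactly zero is
#' classed \code{"uninformative"} (no evidence of benefit).
#'
#' @param dmean numeric vector of DMEAN values.
#' @param p numeric vector of Mann-Whitney p-values in \code{[0, 1]}.
#' @param alpha significance threshold, default 0.05.
#' @return Character vector in
#'   \code{c("strong", "weak", "uninformative", "interfering")}.
#' @export
classifyVariable <- function(dmean, p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  ifelse(dmean < 0,
         ifelse(p < alpha, "strong", "weak"),
         ifelse(dmean > 0,
                ifelse(p < alpha, "interfering", "uninformative"),
                "uninformative"))
}

#' Greedy backward elimination of retained variables
#'
#' Starting from the retained set, repeatedly computes the RMSECV
#' \eqn{\theta_t} of the current set and the leave-one-variable-out values
#' \eqn{\theta_{-i}}; while \eqn{\min_i \theta_{-i} \le \theta_t} the
#' variable whose removal gives the minimum is dropped (ties to the lowest
#' index).  Stops when every removal would raise the error, or when a
#' single variable remains.
#'
#' @param X samples-by-variables matrix (all candidate columns).
#' @param y numeric target.
#' @param vars integer column indices of the retained variables.
#' @param cfg an [irivConfig()].
#' @param folds optional fixed fold labels.
#' @return List with \code{vars} (surviving indices), \code{rmsecv} (final
#'   \eqn{\theta_t}) and \code{trace} (data.frame of removal steps).
#' @export
backwardEliminate <- function(X, y, vars, cfg = irivConfig(), folds = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(vars) == 0L) stop("'vars' must be nonempty")
  if (is.null(folds)) folds <- makeFolds(nrow(X), cfg$cvFolds, cfg$seed)
  folds <- as.integer(folds)
  vars <- as.integer(vars)
  steps <- list()
  theta <- .cppSubsetRmsecv(X, y, vars, folds, cfg$maxPlsFactors)
  while (length(vars) > 1L) {
    thMinus <- vapply(seq_along(vars), function(i)
      .cppSubsetRmsecv(X, y, vars[-i], folds, cfg$maxPlsFactors), numeric(1))
    # ties within floating-point noise resolve toward removal (parsimony),
    # so an exact duplicate column is always dropped
    if (min(thMinus) > theta + 1e-12 * max(1, theta)) break
    drop_i <- which.min(thMinus)
    steps[[length(steps) + 1L]] <-
      data.frame(removed = vars[drop_i], rmsecv_before = theta,
                 rmsecv_after = thMinus[drop_i])
    vars <- vars[-drop_i]
    theta <- thMinus[drop_i]
  }
  list(vars = vars, rmsecv = theta,
       trace = if (length(steps)) do.call(rbind, steps) else
         data.frame(removed = integer(), rmsecv_before = numeric(),
                    rmsecv_after = numeric()))
}

#' Run the full IRIV selector on a SpectrumSet
#'
#' Iterates score -> classify -> retain \{strong, weak\} until a round
#' produces no uninformative or interfering variables (or \code{maxRounds}
#' is hit), re-drawing the balanced design matrix each round from the run
#' seed, then applies backward elimination to the survivors.  The fold
#' partition is drawn once per run so all sub-model RMSECVs are comparable.
#'
#' @param ss a [SpectrumSet-class] with a target attached (or a
#'   samples-by-bands matrix, then \code{y} and \code{bands} are required).
#' @param cfg an [irivConfig()].
#' @param y,bands target vector and band wavelengths when \code{ss} is a
#'   bare matrix.
#' @param verbose print per-round retention counts.
#' @return An [IrivResult-class].
#' @examples
#' \donttest{
#' fx <- makeFixture("lab-small", seed = 7)
#' res <- runIriv(fx$spectra, irivConfig(nRows = 100, seed = 7))
#' finalBands(res)
#' }
#' @export
runIriv <- function(ss, cfg = irivConfig(), y = NULL, bands = NULL,
                    verbose = FALSE) {
  if (methods::is(ss, "SpectrumSet")) {
    y <- targetValues(ss)
    if (is.null(y)) stop("SpectrumSet has no target attached")
    bands <- wavelengths(ss)
    X <- reflectance(ss)
  } else {
    X <- as.matrix(ss)
    if (is.null(y)) stop("'y' is required when 'ss' is a matrix")
    if (is.null(bands)) bands <- seq_len(ncol(X))
  }
  n <- nrow(X)
  if (n < cfg$cvFolds)
    stop("fewer samples (", n, ") than cross-validation folds (",
         cfg$cvFolds, ")")
  folds <- makeFolds(n, cfg$cvFolds, cfg$seed)
  active <- seq_len(ncol(X))
  rounds <- list()
  eliminated <- list()
  counts <- integer()
  for (r in seq_len(cfg$maxRounds)) {
    A <- generateDesignMatrix(length(active), cfg$nRows, cfg$seed + 1000L * r)
    sc <- scoreVariables(X[, active, drop = FALSE], y, A, cfg, folds)
    cls <- classifyVariable(sc$dmean, sc$p, cfg$alpha)
    rounds[[r]] <- data.frame(wavelength = bands[active], dmean = sc$dmean,
                              p = sc$p, class = cls)
    keep <- cls %in% c("strong", "weak")
    if (!any(keep)) {
      err <- simpleError(paste0("all variables eliminated in round ", r))
      err$rounds <- rounds
      stop(err)
    }
    eliminated[[r]] <- bands[active[!keep]]
    active <- active[keep]
    counts[r] <- length(active)
    if (verbose)
      message("round ", r, ": ", length(active), " variables retained")
    if (all(keep)) break
  }
  be <- backwardEliminate(X, y, active, cfg, folds)
  methods::new("IrivResult", rounds = rounds, retainedCounts = counts,
               eliminatedTrace = eliminated, backwardTrace = be$trace,
               finalBands = as.numeric(bands[be$vars]),
               finalRmsecv = be$rmsecv, config = unclass(cfg))
}

#' @rdname IrivResult-class
#' @param x an [IrivResult-class].
#' @export
setMethod("finalBands", "IrivResult", function(x) x@finalBands)

setMethod("show", "IrivResult", function(object) {
  cat("IrivResult:", length(object@rounds), "rounds, retained counts:",
      paste(object@retainedCounts, collapse = " -> "), "\n")
  cat("  final bands (", length(object@finalBands), "): ",
      paste(formatWavelength(object@finalBands), collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  final RMSECV: %.4g\n", object@finalRmsecv))
})
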