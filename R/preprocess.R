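#' Gaussian filtering of spectra over an ordered band sequence
#'
#' Discrete Gaussian smoothing with weights \eqn{\exp(-d^2 / 2\sigma^2)} in
#' band-index units, truncated at radius \code{ceiling(3*sigma)} and
#' renormalized to sum to one.  At the sequence edges only in-range taps are
#' used (again renormalized), so no out-of-range reflectance is invented.
#' Because every output is a convex combination of inputs the filter
#' preserves constant sequences exactly and is linear in its input.
#'
#' @param values numeric vector, or samples-by-bands matrix filtered rowwise.
#' @param sigma kernel width in band-index units (> 0); default 1.
#' @return Filtered object of the same shape.
#' @export
gaussianFilter <- function(values, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive number")
  vec <- is.null(dim(values))
  x <- if (vec) matrix(values, nrow = 1) else as.matrix(values)
  k <- ncol(x)
  if (k < 1L) stop("at least one band is required")
  W <- gaussianWeights(k, sigma)
  out <- x %*% t(W)
  if (vec) drop(out) else { dimnames(out) <- dimnames(x); out }
}

# internal: k x k row-stochastic smoothing matrix (row i = weights for band i)
gaussianWeights <- function(k, sigma) {
  r <- ceiling(3 * sigma)
  idx <- seq_len(k)
  W <- matrix(0, k, k)
  for (i in idx) {
    taps <- idx[abs(idx - i) <= r]
    w <- exp(-((taps - i)^2) / (2 * sigma^2))
    W[i, taps] <- w / sum(w)
  }
  W
}

#' First-derivative features over a retained-band sequence
#'
#' Forward difference quotient between consecutive bands of the sequence:
#' feature \eqn{j} is \eqn{(x_{j+1} - x_j) / (\lambda_{j+1} - \lambda_j)}
#' (per-nm units), named \code{FD_<upper>-<lower>} after its band pair.
#' When applied to an IRIV-retained band set, consecutive retained bands
#' form the pairs, which is how pair-labelled characteristic features such
#' as \code{GFA_849-769} arise from a retained set containing 769 and 849 nm.
#'
#' @param values numeric samples-by-bands matrix (or vector of one sample).
#' @param wavelengths strictly increasing band centers, nm.
#' @param prefix feature-name prefix, default \code{"FD"}.
#' @return A [FeatureBlock-class] of kind \code{"FD"} with
#'   \code{length(wavelengths) - 1} features.
#' @export
firstDerivative <- function(values, wavelengths, prefix = "FD") {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  wavelengths <- as.numeric(wavelengths)
  k <- length(wavelengths)
  if (ncol(values) != k)
    stop("values has ", ncol(values), " columns but ", k, " wavelengths given")
  if (k < 2L) stop("at least two bands are required for a derivative")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  dl <- diff(wavelengths)
  fd <- (values[, -1, drop = FALSE] - values[, -k, drop = FALSE]) /
    matrix(dl, nrow(values), k - 1L, byrow = TRUE)
  hi <- wavelengths[-1]; lo <- wavelengths[-k]
  nm <- paste0(prefix, "_", formatWavelength(hi), "-", formatWavelength(lo))
  colnames(fd) <- nm
  rownames(fd) <- rownames(values)
  methods::new("FeatureBlock", kind = "FD", values = fd,
               bands = cbind(upper = hi, lower = lo))
}

#' The GF -> FD -> GFA preprocessing cascade
#'
#' Applies, per sample, Gaussian filtering (GF) over the retained-band
#' sequence, the first derivative (FD) of the filtered sequence over
#' consecutive retained bands, and Gaussian filtering again (GFA) of the FD
#' sequence.  For k retained bands the blocks hold k, k-1 and k-1 features.
#'
#' @param x a [SpectrumSet-class] restricted to the retained bands, or a
#'   samples-by-bands matrix (then \code{wavelengths} is required).
#' @param sigma Gaussian kernel width in retained-band index units.
#' @param wavelengths band centers when \code{x} is a bare matrix.
#' @return Named list of [FeatureBlock-class]: \code{GF}, \code{FD},
#'   \code{GFA}.
#' @examples
#' ss <- makeFixture("lab-small")$spectra
#' sub <- ss[wavelengths(ss) %in% c(560, 990, 1410), ]
#' sapply(gfaCascade(sub), function(b) ncol(featureValues(b)))
#' @export
gfaCascade <- function(x, sigma = 1, wavelengths = NULL) {
  if (methods::is(x, "SpectrumSet")) {
    wavelengths <- wavelengths(x)
    x <- reflectance(x)
  }
  if (is.null(wavelengths))
    stop("'wavelengths' is required when 'x' is a matrix")
  x <- as.matrix(x)
  if (length(wavelengths) < 2L)
    stop("at least two retained bands are required (FD is undefined for one)")
  gf <- gaussianFilter(x, sigma)
  colnames(gf) <- paste0("GF_", formatWavelength(wavelengths))
  gfBlock <- methods::new("FeatureBlock", kind = "GF", values = gf,
                          bands = cbind(upper = wavelengths, lower = NA_real_))
  fdBlock <- firstDerivative(gf, wavelengths)
  gfa <- gaussianFilter(fdBlock@values, sigma)
  colnames(gfa) <- sub("^FD_", "GFA_", colnames(fdBlock@values))
  gfaBlock <- methods::new("FeatureBlock", kind = "GFA", values = gfa,
                           bands = fdBlock@bands)
  list(GF = gfBlock, FD = fdBlock, GFA = gfaBlock)
}

#' Train-statistics standardization (z-scoring)
#'
#' Centers and scales each column by the mean and population standard
#' deviation of the \emph{training} rows only, applying the same transform
#' to the test rows, so that no validation information leaks into the
#' scaling.  Population sd (divide by n) is used, matching the common
#' machine-learning StandardScaler convention; a zero-variance training
#' column is an error (naming the column) rather than a silent division by
#' zero.
#'
#' @param train numeric matrix (>= 2 rows).
#' @param test optional numeric matrix with the same columns.
#' @return List with \code{train}, \code{test} (or \code{NULL}),
#'   \code{center} and \code{scale}.
#' @export
standardize <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("at least two training samples are required")
  ctr <- colMeans(train)
  scl <- sqrt(colMeans(sweep(train, 2, ctr)^2))
  if (any(scl == 0)) {
    bad <- colnames(train)[scl == 0]
    if (is.null(bad)) bad <- which(scl == 0)
    stop("zero-variance training column(s): ", paste(bad, collapse = ", "))
  }
  scale2 <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  list(train = scale2(train),
       test = if (is.null(test)) NULL else scale2(as.matrix(test)),
       center = ctr, scale = scl)
}

#' @rdname FeatureBlock-accessors
#' @title Accessors for FeatureBlock
#' @param x a [FeatureBlock-class].
#' @return \code{featureNames}: character vector; \code{featureValues}:
#'   samples-by-features matrix.
#' @export
setMethod("featureNames", "FeatureBlock", function(x) colnames(x@values))

#' @rdname FeatureBlock-accessors
#' @export
setMethod("featureValues", "FeatureBlock", function(x) x@values)

setMethod("show", "FeatureBlock", function(object) {
  cat(sprintf("FeatureBlock kind=%s: %d samples x %d features\n",
              object@kind, nrow(object@values), ncol(object@values)))
})
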