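#' SPXY calibration/validation partitioning
#'
#' Sample-set partitioning based on joint x-y distances.  The pairwise
#' distance is the sum of the Euclidean distance on the feature matrix and
#' the absolute difference on the target, each normalized by its maximum:
#' \deqn{d(i,j) = d_x(i,j)/\max d_x + d_y(i,j)/\max d_y.}
#' Selection is Kennard-Stone style and fully deterministic: the pair with
#' the largest joint distance seeds the calibration set, then the sample
#' maximizing its minimum distance to the selected set is added until
#' \code{nCal} samples are chosen; ties go to the lowest original index.
#' The remainder forms the validation set.  Distances are computed on the
#' features as given (typically raw reflectance, before any scaling).
#'
#' @param X numeric samples-by-features matrix.
#' @param y numeric target vector.
#' @param nCal calibration-set size, \code{2 <= nCal < nrow(X)}.
#' @return A [SplitResult-class].
#' @examples
#' fx <- makeFixture("lab-small")
#' sp <- spxySplit(reflectance(fx$spectra), targetValues(fx$spectra), 42)
#' length(calibrationIdx(sp))  # 42
#' @export
spxySplit <- function(X, y, nCal) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("'y' length must match rows of 'X'")
  nCal <- as.integer(nCal)
  if (nCal < 2L || nCal >= n)
    stop("'nCal' must satisfy 2 <= nCal < n_samples")
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0)
    stop("all samples are identical in both X and y; SPXY is undefined")
  d <- (if (mx > 0) dx / mx else 0) + (if (my > 0) dy / my else 0)
  # seed pair: maximum joint distance, ties to lowest (row, col) indices
  which2 <- which(d == max(d), arr.ind = TRUE)
  which2 <- which2[order(which2[, 1], which2[, 2]), , drop = FALSE]
  sel <- sort(unname(which2[1, ]))
  while (length(sel) < nCal) {
    rest <- setdiff(seq_len(n), sel)
    minDist <- apply(d[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(minDist)])   # which.max: lowest index wins
  }
  methods::new("SplitResult", calibration = as.integer(sel),
               validation = as.integer(setdiff(seq_len(n), sel)))
}

#' @rdname SplitResult-class
#' @param x a [SplitResult-class].
#' @export
setMethod("calibrationIdx", "SplitResult", function(x) x@calibration)

#' @rdname SplitResult-class
#' @export
setMethod("validationIdx", "SplitResult", function(x) x@validation)

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d calibration / %d validation samples\n",
              length(object@calibration), length(object@validation)))
})
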