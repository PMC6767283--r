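#' Spearman rank correlation
#'
#' Product-moment correlation applied to average-ranked data (ties receive
#' their mean rank), i.e. Spearman's rho, used to screen derived spectral
#' features against the target concentration.  Constant input has no
#' defined rank correlation and is an error rather than a silent zero.
#'
#' @param x,y numeric vectors of equal length (>= 3), no missing values.
#' @return Correlation in \code{[-1, 1]}.
#' @examples
#' spearman(1:4, c(2, 4, 5, 9))   # 1: perfect monotone
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3L) stop("at least 3 samples are required")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("missing or non-finite values are not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation is undefined for a constant vector")
  cor(x, y, method = "spearman")
}

#' Screen cascade features by Spearman correlation
#'
#' Computes Spearman's rho against the target for every feature of every
#' block of the GF/FD/GFA cascade and retains those with
#' \code{|rho| > threshold} (strict inequality).  Retained features are
#' ordered by block (GF, FD, GFA) and then by (upper) source wavelength.
#' When no feature clears the threshold an empty [FeatureSet-class] is
#' returned (with a message); the caller decides any fallback.
#'
#' @param blocks named list of [FeatureBlock-class] as produced by
#'   [gfaCascade()] (any subset of GF/FD/GFA).
#' @param y numeric target, same sample count as the blocks.
#' @param threshold absolute-correlation cutoff, default 0.6.
#' @return A [FeatureSet-class] carrying values, per-feature rho and block
#'   provenance.
#' @export
selectFeatures <- function(blocks, y, threshold = 0.6) {
  if (methods::is(blocks, "FeatureBlock")) blocks <- list(blocks)
  ordKind <- c("GF", "FD", "GFA")
  kinds <- vapply(blocks, function(b) b@kind, character(1))
  blocks <- blocks[order(match(kinds, ordKind))]
  rows <- list()
  vals <- list()
  for (b in blocks) {
    if (nrow(b@values) != length(y))
      stop("block '", b@kind, "' has ", nrow(b@values),
           " samples but target has ", length(y))
    if (ncol(b@values) == 0L) next
    r <- apply(b@values, 2, spearman, y = y)
    ord <- order(b@bands[, 1])
    keep <- ord[abs(r[ord]) > threshold]
    if (length(keep) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = colnames(b@values)[keep], kind = b@kind,
      wavelength = b@bands[keep, 1], wavelength2 = b@bands[keep, 2],
      spearman_r = unname(r[keep]), stringsAsFactors = FALSE)
    vals[[length(vals) + 1L]] <- b@values[, keep, drop = FALSE]
  }
  n <- if (length(blocks)) nrow(blocks[[1]]@values) else length(y)
  if (length(rows) == 0L) {
    message("no feature exceeds |rho| > ", threshold,
            "; returning an empty FeatureSet")
    info <- data.frame(name = character(), kind = character(),
                       wavelength = numeric(), wavelength2 = numeric(),
                       spearman_r = numeric(), stringsAsFactors = FALSE)
    return(methods::new("FeatureSet",
                        values = matrix(numeric(), n, 0),
                        info = info, threshold = threshold))
  }
  info <- do.call(rbind, rows)
  rownames(info) <- NULL
  values <- do.call(cbind, vals)
  methods::new("FeatureSet", values = values, info = info,
               threshold = threshold)
}

#' @rdname FeatureSet-class
#' @param x a [FeatureSet-class].
#' @export
setMethod("featureNames", "FeatureSet", function(x) x@info$name)

#' @rdname FeatureSet-class
#' @export
setMethod("featureValues", "FeatureSet", function(x) x@values)

#' Per-feature screening table of a FeatureSet
#'
#' @param fs a [FeatureSet-class].
#' @return data.frame with name, kind, wavelength(s) and Spearman rho.
#' @export
featureInfo <- function(fs) fs@info

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d samples x %d features (|rho| > %s)\n",
              nrow(object@values), ncol(object@values),
              format(object@threshold)))
  if (nrow(object@info)) {
    df <- object@info
    df$spearman_r <- round(df$spearman_r, 3)
    print(utils::head(df, 12), row.names = FALSE)
    if (nrow(df) > 12) cat("  ...", nrow(df) - 12, "more\n")
  }
})
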