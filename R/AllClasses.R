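#' @import methods
#' @importFrom stats sd cor median quantile rnorm runif predict coef wilcox.test uniroot
#' @importFrom utils read.csv write.csv count.fields modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @useDynLib irivsca, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' SpectrumSet: reflectance spectra with an optional per-sample target
#'
#' The central data container of the package, extending
#' \linkS4class{SummarizedExperiment}.  Spectral bands are rows (with their
#' wavelength in nm in \code{rowData}) and samples are columns; the single
#' assay \code{"reflectance"} holds unitless reflectance in \code{[0, 1]}.
#' The optional target (e.g. soil arsenic concentration in ug/g) lives in
#' \code{colData(x)$target}.
#'
#' Validity requires strictly increasing, finite wavelengths matching the
#' assay row count, finite non-negative reflectance, and (when present) a
#' finite target of length equal to the number of samples.
#'
#' @seealso [SpectrumSet()] for construction from a samples-by-bands matrix,
#'   [readSpectra()] to load from CSV, [trimEdges()] for edge-band removal.
#' @name SpectrumSet-class
#' @aliases SpectrumSet-class
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
  msg <- character()
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'reflectance' is required")
  wl <- SummarizedExperiment::rowData(object)$wavelength
  if (is.null(wl)) {
    msg <- c(msg, "rowData column 'wavelength' is required")
  } else {
    if (length(wl) != nrow(object))
      msg <- c(msg, "wavelength length must equal the number of bands")
    if (any(!is.finite(wl)))
      msg <- c(msg, "wavelengths must be finite")
    else if (length(wl) > 1L && any(diff(wl) <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing")
  }
  if (length(msg) == 0L) {
    refl <- SummarizedExperiment::assay(object, "reflectance")
    if (any(!is.finite(refl)))
      msg <- c(msg, "reflectance values must all be finite")
    else if (any(refl < 0))
      msg <- c(msg, "negative reflectance values are not allowed")
    tg <- SummarizedExperiment::colData(object)$target
    if (!is.null(tg)) {
      if (length(tg) != ncol(object))
        msg <- c(msg, "target length must equal the number of samples")
      else if (any(!is.finite(tg)))
        msg <- c(msg, "target values must all be finite")
    }
    ids <- colnames(object)
    if (is.null(ids) || anyDuplicated(ids))
      msg <- c(msg, "sample ids must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param reflectance numeric matrix, samples x bands, values in \code{[0,1]}.
#' @param wavelengths numeric vector of band centers in nm, one per column of
#'   \code{reflectance}; must be strictly increasing.
#' @param sampleIds optional character vector of unique sample labels
#'   (default \code{"S1"..."Sn"}).
#' @param target optional numeric vector of per-sample concentrations (ug/g).
#' @return A [SpectrumSet-class] object.
#' @examples
#' ss <- SpectrumSet(matrix(runif(15, 0.1, 0.5), 3, 5), 400:404)
#' wavelengths(ss)
#' @export
SpectrumSet <- function(reflectance, wavelengths, sampleIds = NULL,
                        target = NULL) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(reflectance) != length(wavelengths))
    stop("number of reflectance columns (", ncol(reflectance),
         ") does not match number of wavelengths (", length(wavelengths), ")")
  n <- nrow(reflectance)
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(n))
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]
  assay <- t(reflectance[, ord, drop = FALSE])
  dimnames(assay) <- list(formatWavelength(wavelengths), sampleIds)
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  if (!is.null(target)) cd$target <- as.numeric(target)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = assay),
    rowData = S4Vectors::DataFrame(wavelength = wavelengths),
    colData = cd)
  methods::new("SpectrumSet", se)
}

#' FeatureBlock: one derived-feature block of the GF/FD/GFA cascade
#'
#' Holds a samples-by-features matrix of derived spectral features of a
#' single kind: \code{"GF"} (Gaussian-filtered reflectance, one feature per
#' retained band), \code{"FD"} (first-derivative of GF over consecutive
#' retained bands) or \code{"GFA"} (Gaussian filtering of the FD sequence).
#' Feature names follow the field convention \code{GF_486},
#' \code{FD_849-769}, \code{GFA_849-769}: a single wavelength for GF and the
#' ordered (upper-lower) band pair for FD/GFA.
#'
#' @slot kind one of \code{"GF"}, \code{"FD"}, \code{"GFA"}.
#' @slot values numeric matrix, samples x features, colnames = feature names.
#' @slot bands numeric matrix, features x 2: upper and lower source
#'   wavelength (lower is \code{NA} for GF features).
#' @name FeatureBlock-class
#' @exportClass FeatureBlock
setClass("FeatureBlock",
         representation(kind = "character", values = "matrix",
                        bands = "matrix"))

setValidity("FeatureBlock", function(object) {
  msg <- character()
  if (!object@kind %in% c("GF", "FD", "GFA"))
    msg <- c(msg, "kind must be one of 'GF', 'FD', 'GFA'")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "values must carry feature names as colnames")
  else if (anyDuplicated(colnames(object@values)))
    msg <- c(msg, "feature names must be unique")
  if (nrow(object@bands) != ncol(object@values) || ncol(object@bands) != 2L)
    msg <- c(msg, "bands must be a (n_features x 2) matrix")
  if (length(msg)) msg else TRUE
})

#' FeatureSet: screened characteristic-band features
#'
#' Result of Spearman-correlation screening ([selectFeatures()]): the
#' retained derived features (columns of \code{values}), each annotated with
#' its originating block kind, source wavelengths and Spearman coefficient
#' against the target.
#'
#' @slot values numeric matrix, samples x retained features.
#' @slot info data.frame with columns \code{name}, \code{kind},
#'   \code{wavelength}, \code{wavelength2}, \code{spearman_r}.
#' @slot threshold numeric, the |r| screening threshold used.
#' @name FeatureSet-class
#' @exportClass FeatureSet
setClass("FeatureSet",
         representation(values = "matrix", info = "data.frame",
                        threshold = "numeric"))

setValidity("FeatureSet", function(object) {
  msg <- character()
  need <- c("name", "kind", "wavelength", "wavelength2", "spearman_r")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@info) != ncol(object@values))
      msg <- c(msg, "info rows must match value columns")
    if (anyDuplicated(object@info$name))
      msg <- c(msg, "feature names must be unique across blocks")
  }
  if (length(msg)) msg else TRUE
})

#' SplitResult: an SPXY calibration/validation partition
#'
#' @slot calibration integer indices of calibration samples.
#' @slot validation integer indices of validation samples.
#' @name SplitResult-class
#' @exportClass SplitResult
setClass("SplitResult",
         representation(calibration = "integer", validation = "integer"))

setValidity("SplitResult", function(object) {
  if (length(intersect(object@calibration, object@validation)) > 0)
    return("calibration and validation sets must be disjoint")
  TRUE
})

#' IrivResult: trace and outcome of an IRIV run
#'
#' @slot rounds list of per-round data.frames (one row per variable still in
#'   play: wavelength, dmean, p, class).
#' @slot retainedCounts integer vector, variables retained after each round.
#' @slot eliminatedTrace list of wavelengths eliminated at each round.
#' @slot backwardTrace data.frame of the backward-elimination steps
#'   (removed wavelength, RMSECV before/after).
#' @slot finalBands numeric, wavelengths surviving backward elimination.
#' @slot finalRmsecv numeric, five-fold RMSECV of the final band set.
#' @slot config the [irivConfig()] used.
#' @name IrivResult-class
#' @exportClass IrivResult
setClass("IrivResult",
         representation(rounds = "list", retainedCounts = "integer",
                        eliminatedTrace = "list", backwardTrace = "data.frame",
                        finalBands = "numeric", finalRmsecv = "numeric",
                        config = "list"))
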