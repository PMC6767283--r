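#' Accessors for SpectrumSet
#'
#' \code{wavelengths()} returns the band centers in nm; \code{reflectance()}
#' returns the samples-by-bands reflectance matrix in the orientation used
#' throughout chemometrics (the assay itself is stored bands-by-samples);
#' \code{sampleIds()} the sample labels; \code{targetValues()} the per-sample
#' target concentrations (ug/g) or \code{NULL} when absent.
#'
#' @param x a [SpectrumSet-class].
#' @param value numeric replacement target vector.
#' @return See individual descriptions.
#' @name SpectrumSet-accessors
NULL

#' @rdname SpectrumSet-accessors
#' @export
setMethod("wavelengths", "SpectrumSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavelength))

#' @rdname SpectrumSet-accessors
#' @export
setMethod("reflectance", "SpectrumSet", function(x)
  t(SummarizedExperiment::assay(x, "reflectance")))

#' @rdname SpectrumSet-accessors
#' @export
setMethod("sampleIds", "SpectrumSet", function(x) colnames(x))

#' @rdname SpectrumSet-accessors
#' @export
setMethod("targetValues", "SpectrumSet", function(x) {
  tg <- SummarizedExperiment::colData(x)$target
  if (is.null(tg)) NULL else as.numeric(tg)
})

#' @rdname SpectrumSet-accessors
#' @export
setReplaceMethod("targetValues", "SpectrumSet", function(x, value) {
  SummarizedExperiment::colData(x)$target <- as.numeric(value)
  methods::validObject(x)
  x
})

setMethod("show", "SpectrumSet", function(object) {
  wl <- wavelengths(object)
  cat("SpectrumSet with", ncol(object), "samples x", nrow(object), "bands\n")
  if (length(wl))
    cat(sprintf("  wavelengths: %s - %s nm\n", formatWavelength(min(wl)),
                formatWavelength(max(wl))))
  cat("  target:", if (is.null(targetValues(object))) "absent" else
    sprintf("present (mean %.3g ug/g)", mean(targetValues(object))), "\n")
})

#' Remove noisy edge bands
#'
#' Vis-NIR spectrometer fringes are noisy; the conventional cleanup retains
#' the closed wavelength interval \code{[low, high]} (defaults 400-2399 nm,
#' which reduces the 2151-band 1-nm laboratory grid to 2000 bands).
#'
#' @param x a [SpectrumSet-class].
#' @param low,high interval bounds in nm (closed on both sides).
#' @return The trimmed [SpectrumSet-class]; sample rows are unchanged.
#' @examples
#' ss <- SpectrumSet(matrix(0.3, 2, 2151), 350:2500)
#' nrow(trimEdges(ss))  # 2000
#' @rdname trimEdges
#' @export
setMethod("trimEdges", "SpectrumSet", function(x, low = 400, high = 2399) {
  if (low >= high) stop("'low' must be smaller than 'high'")
  keep <- which(wavelengths(x) >= low & wavelengths(x) <= high)
  if (length(keep) == 0L)
    stop("no bands fall inside [", low, ", ", high, "] nm")
  x[keep, ]
})

# internal: canonical wavelength label ("849", "619.6") used in feature names
formatWavelength <- function(w)
  vapply(w, function(x) format(x, trim = TRUE, scientific = FALSE,
                               drop0trailing = TRUE), character(1))
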