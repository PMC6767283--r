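#' Read a spectral table from CSV
#'
#' The on-disk format is a plain delimited table.  With
#' \code{layout = "samples-as-rows"} the header holds the numeric
#' wavelengths (nm) and each row is one sample; an optional leading
#' non-numeric column (e.g. \code{sample_id}) supplies sample labels.  With
#' \code{layout = "samples-as-columns"} the first column holds the
#' wavelengths and the remaining headers are sample ids.  Wavelength labels
#' are kept as decimal nm exactly as printed (field instruments have
#' non-integer band centers such as 619.6); columns are reordered so
#' wavelengths are ascending.
#'
#' @param path CSV file path.
#' @param layout \code{"samples-as-rows"} (default) or
#'   \code{"samples-as-columns"}.
#' @param target optional numeric vector attached as the target.
#' @return A validated [SpectrumSet-class].
#' @export
readSpectra <- function(path, layout = c("samples-as-rows",
                                         "samples-as-columns"),
                        target = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L)
    stop("ragged CSV: row(s) ", paste(which(nf != nf[1]), collapse = ", "),
         " have a different field count than the header")
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "samples-as-rows") {
    hdr <- names(df)
    wl <- suppressWarnings(as.numeric(hdr))
    ids <- NULL
    if (is.na(wl[1]) && length(hdr) > 1L) {   # leading id column
      ids <- as.character(df[[1]])
      df <- df[, -1, drop = FALSE]
      hdr <- hdr[-1]
      wl <- wl[-1]
    }
    if (any(is.na(wl)))
      stop("non-numeric wavelength header(s): ",
           paste(hdr[is.na(wl)], collapse = ", "))
    if (anyDuplicated(wl))
      stop("duplicated wavelength(s): ",
           paste(unique(wl[duplicated(wl)]), collapse = ", "))
    mat <- as.matrix(df)
    if (!is.numeric(mat)) stop("non-numeric reflectance values in ", path)
    SpectrumSet(mat, wl, sampleIds = ids, target = target)
  } else {
    wl <- suppressWarnings(as.numeric(df[[1]]))
    if (any(is.na(wl)))
      stop("non-numeric wavelength value(s) in first column: row(s) ",
           paste(which(is.na(wl)), collapse = ", "))
    if (anyDuplicated(wl))
      stop("duplicated wavelength(s): ",
           paste(unique(wl[duplicated(wl)]), collapse = ", "))
    mat <- t(as.matrix(df[, -1, drop = FALSE]))
    if (!is.numeric(mat)) stop("non-numeric reflectance values in ", path)
    SpectrumSet(mat, wl, sampleIds = names(df)[-1], target = target)
  }
}

#' Write a SpectrumSet to CSV (samples as rows)
#'
#' @param x a [SpectrumSet-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(x, path) {
  df <- data.frame(sample_id = sampleIds(x),
                   formatNum(reflectance(x)), check.names = FALSE)
  names(df) <- c("sample_id", formatWavelength(wavelengths(x)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-sample target tables
#'
#' Targets are stored as a two-column CSV (\code{sample_id,value}); every
#' value must be present and finite.
#'
#' @param path CSV file path.
#' @return \code{readTargets}: a named numeric vector.
#' @export
readTargets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("target table needs columns sample_id,value")
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(v) | !is.finite(v)))
    stop("missing or non-finite target value(s) at row(s): ",
         paste(which(is.na(v) | !is.finite(v)), collapse = ", "))
  stats::setNames(v, as.character(df[[1]]))
}

#' @rdname readTargets
#' @param values named numeric vector of targets.
#' @export
writeTargets <- function(values, path) {
  ids <- names(values)
  if (is.null(ids)) ids <- paste0("S", seq_along(values))
  write.csv(data.frame(sample_id = ids, value = formatNum(values)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a FeatureSet as CSV
#'
#' One row per retained feature with its name, block kind, source
#' wavelength(s) and Spearman coefficient (mirroring the usual
#' characteristic-band table layout), followed by one column per sample with
#' the feature values.  Values are printed with 17 significant digits so a
#' write/read round trip reproduces the doubles bit-identically.
#'
#' @param fs a [FeatureSet-class].
#' @param path CSV path.
#' @return \code{writeFeatures}: \code{path} invisibly;
#'   \code{readFeatures}: the restored [FeatureSet-class].
#' @export
writeFeatures <- function(fs, path) {
  vals <- t(fs@values)                       # features x samples
  sample_cols <- if (ncol(vals)) formatNum(vals) else
    matrix(character(), nrow = nrow(fs@info), ncol = 0)
  info <- fs@info
  for (j in c("wavelength", "wavelength2", "spearman_r"))
    info[[j]] <- formatNum(info[[j]])
  df <- cbind(info, as.data.frame(sample_cols, stringsAsFactors = FALSE))
  ids <- rownames(fs@values)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(fs@values)))
  names(df) <- c(names(fs@info), ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("name", "kind", "wavelength", "wavelength2", "spearman_r")
  if (!all(meta %in% names(df)))
    stop("not a FeatureSet table: missing column(s) ",
         paste(setdiff(meta, names(df)), collapse = ", "))
  info <- df[, meta, drop = FALSE]
  info$name <- as.character(info$name)
  info$kind <- as.character(info$kind)
  samp <- setdiff(names(df), meta)
  vals <- t(as.matrix(df[, samp, drop = FALSE]))
  if (nrow(info) == 0L) vals <- matrix(numeric(), length(samp), 0)
  colnames(vals) <- info$name
  rownames(vals) <- samp
  methods::new("FeatureSet", values = vals, info = info, threshold = NA_real_)
}

# internal: full-precision text rendering for round-trip-stable CSVs
formatNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA
  attributes(out) <- attributes(x)[c("dim", "dimnames")]
  out
}
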