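# shared helpers: tiny in-code fixtures for the io and selector tests

# a small SpectrumSet with known values
tinySpectra <- function(n = 3, wl = 400:404, seed = 42) {
  set.seed(seed)
  SpectrumSet(matrix(runif(n * length(wl), 0.1, 0.6), n), wl)
}

# write a samples-as-rows CSV and return its path
writeTempSpectraCsv <- function(mat, wl, ids = NULL) {
  path <- tempfile(fileext = ".csv")
  df <- as.data.frame(mat)
  names(df) <- as.character(wl)
  if (!is.null(ids)) df <- cbind(sample_id = ids, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# simulation config for a small planted-band problem (unconstrained noise)
smallPlantedConfig <- function(seed, nBands = 40, planted = c(500, 900, 1400, 2000),
                               effect = 0.014, noiseSd = 0.004) {
  wl <- seq(400, by = 50, length.out = nBands)
  simConfig(nSamples = 63, grid = wl, plantedBands = planted,
            effectSizes = effect, baseDepth = 0.03, featureWidth = 10,
            noiseSd = noiseSd, scatterSd = 0, baselineSd = 0, seed = seed)
}
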