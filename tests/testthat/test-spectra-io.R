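test_that("reading a samples-as-rows CSV reproduces the table", {
  mat <- matrix(seq(0.1, 0.6, length.out = 15), 3, 5)
  path <- writeTempSpectraCsv(mat, 400:404)
  ss <- readSpectra(path)
  expect_s4_class(ss, "SpectrumSet")
  expect_equal(wavelengths(ss), as.numeric(400:404))
  expect_equal(unname(reflectance(ss)), mat, tolerance = 1e-12)
})

test_that("shuffled wavelength columns sort to the identical SpectrumSet", {
  mat <- matrix(runif(15, 0.1, 0.5), 3, 5)
  ord <- c(3, 1, 5, 2, 4)
  p1 <- writeTempSpectraCsv(mat, 400:404)
  p2 <- writeTempSpectraCsv(mat[, ord], (400:404)[ord])
  expect_equal(reflectance(readSpectra(p2)), reflectance(readSpectra(p1)))
  expect_equal(wavelengths(readSpectra(p2)), wavelengths(readSpectra(p1)))
})

test_that("duplicate and malformed wavelength headers are rejected by name", {
  mat <- matrix(runif(8, 0.1, 0.5), 2, 4)
  expect_error(readSpectra(writeTempSpectraCsv(mat, c(700, 740, 740, 800))),
               "740")
  expect_error(readSpectra(writeTempSpectraCsv(mat, c("a", "b", "c", "d"))),
               "non-numeric")
  ragged <- tempfile(fileext = ".csv")
  writeLines(c("400,401,402", "0.1,0.2,0.3", "0.1,0.2"), ragged)
  expect_error(readSpectra(ragged), "ragged")
})

test_that("samples-as-columns layout matches the row layout", {
  mat <- matrix(runif(12, 0.1, 0.5), 3, 4)
  p1 <- writeTempSpectraCsv(mat, c(500, 510, 520, 530),
                            ids = c("a", "b", "c"))
  p2 <- tempfile(fileext = ".csv")
  df <- data.frame(wavelength = c(500, 510, 520, 530), t(mat))
  names(df)[-1] <- c("a", "b", "c")
  write.csv(df, p2, row.names = FALSE, quote = FALSE)
  s1 <- readSpectra(p1)
  s2 <- readSpectra(p2, layout = "samples-as-columns")
  expect_equal(reflectance(s1), reflectance(s2), tolerance = 1e-12)
  expect_equal(sampleIds(s2), c("a", "b", "c"))
})

test_that("SpectrumSet validity rejects bad inputs", {
  expect_error(SpectrumSet(matrix(-0.1, 2, 3), c(400, 410, 420)), "negative")
  expect_error(SpectrumSet(matrix(0.2, 2, 3), c(400, 400, 420)), "increasing")
  expect_error(SpectrumSet(matrix(0.2, 2, 3), c(400, 410, 420),
                           target = c(1, NA)), "finite|length")
  expect_error(SpectrumSet(matrix(0.2, 2, 3), c(400, 410)), "does not match")
})

test_that("edge trimming retains the closed interval and is idempotent", {
  ss <- SpectrumSet(matrix(0.3, 2, 2151), 350:2500)
  tr <- trimEdges(ss)
  expect_equal(nrow(tr), 2000L)
  expect_equal(range(wavelengths(tr)), c(400, 2399))
  expect_equal(wavelengths(trimEdges(tr)), wavelengths(tr))
  # wider window is a no-op
  expect_equal(nrow(trimEdges(ss, 0, 5000)), 2151L)
  expect_error(trimEdges(ss, 500, 400), "smaller")
  expect_error(trimEdges(ss, 2600, 3000), "no bands")
})

test_that("trimmed band count equals a brute-force filter on any grid", {
  set.seed(7)
  for (i in 1:3) {
    wl <- sort(sample(seq(350, 2500, by = 0.1), 990))
    ss <- SpectrumSet(matrix(0.3, 2, length(wl)), wl)
    expect_equal(nrow(trimEdges(ss)), sum(wl >= 400 & wl <= 2399))
  }
})

test_that("FeatureSet CSV round trip is bit-identical", {
  fx <- makeFixture("lab-small")
  sub <- fx$spectra[wavelengths(fx$spectra) %in% fx$plantedBands, ]
  fs <- selectFeatures(gfaCascade(sub), targetValues(fx$spectra), 0.6)
  path <- tempfile(fileext = ".csv")
  writeFeatures(fs, path)
  back <- readFeatures(path)
  expect_identical(featureValues(back), featureValues(fs))
  expect_identical(featureInfo(back)$name, featureInfo(fs)$name)
  expect_identical(featureInfo(back)$spearman_r, featureInfo(fs)$spearman_r)
})

test_that("empty FeatureSet round-trips as a header-only file", {
  fx <- makeFixture("lab-small")
  sub <- fx$spectra[wavelengths(fx$spectra) %in% fx$plantedBands, ]
  suppressMessages(
    fs <- selectFeatures(gfaCascade(sub), targetValues(fx$spectra),
                         threshold = 1))
  expect_equal(ncol(featureValues(fs)), 0L)
  path <- tempfile(fileext = ".csv")
  writeFeatures(fs, path)
  back <- readFeatures(path)
  expect_equal(nrow(featureInfo(back)), 0L)
})

test_that("target tables round-trip and reject missing values", {
  v <- c(A = 9.1, B = 10.23456789012345, C = 8.5)
  path <- tempfile(fileext = ".csv")
  writeTargets(v, path)
  expect_identical(readTargets(path), v)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,value", "A,9.1", "B,"), bad)
  expect_error(readTargets(bad), "missing|non-finite")
})
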