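test_that("spearman handles perfect monotone and antitone association", {
  expect_equal(spearman(1:4, 1:4), 1)
  expect_equal(spearman(c(1, 2, 3), c(9, 4, 1)), -1)
  expect_equal(spearman(1:5, exp(1:5)), 1)    # any increasing transform
  expect_error(spearman(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman(1:3, 1:4), "length")
  expect_error(spearman(c(1, NA, 3), 1:3), "finite")
})

test_that("spearman equals Pearson on average ranks, including ties", {
  expect_equal(spearman(c(1, 1, 2), c(1, 2, 3)),
               cor(rank(c(1, 1, 2)), rank(c(1, 2, 3))))
  set.seed(8)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- sample(round(rnorm(n), sample(0:2, 1)))   # coarse rounding -> ties
    y <- sample(round(rnorm(n), sample(0:2, 1)))
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20)
    r <- spearman(x, y)
    expect_equal(spearman(exp(x), y), r, tolerance = 1e-12)
    expect_equal(spearman(x, y^3 + 2 * y), r, tolerance = 1e-12)
  }
})

# helper: build a FeatureBlock whose features have controlled rank association
mkBlock <- function(kind, wl, cols, n = 30) {
  vals <- do.call(cbind, cols)
  colnames(vals) <- if (kind == "GF") paste0(kind, "_", wl) else
    paste0(kind, "_", wl + 10, "-", wl)
  bands <- if (kind == "GF") cbind(upper = wl, lower = NA_real_) else
    cbind(upper = wl + 10, lower = wl)
  methods::new("FeatureBlock", kind = kind, values = vals, bands = bands)
}

test_that("screening keeps exactly the features beyond the threshold", {
  set.seed(12)
  n <- 40
  y <- rnorm(n)
  noise <- function() {                 # redraw until weakly correlated
    v <- rnorm(n)
    while (abs(cor(rank(v), rank(y))) > 0.4) v <- rnorm(n)
    v
  }
  gf <- mkBlock("GF", c(500, 600, 700), list(-y + rnorm(n, 0, 0.1), noise(), exp(y)), n)
  fd <- mkBlock("FD", c(800, 900), list(noise(), noise()), n)
  gfa <- mkBlock("GFA", c(1000, 1100, 1200, 1300),
                 list(y^3, -exp(y), noise(), y + rnorm(n, 0, 0.2)), n)
  fs <- selectFeatures(list(GFA = gfa, FD = fd, GF = gf), y, 0.6)
  info <- featureInfo(fs)
  expect_true(all(abs(info$spearman_r) > 0.6))
  # excluded features all fail the threshold (partition property)
  allR <- c(apply(featureValues(gf), 2, spearman, y = y),
            apply(featureValues(fd), 2, spearman, y = y),
            apply(featureValues(gfa), 2, spearman, y = y))
  excluded <- setdiff(names(allR), info$name)
  expect_true(all(abs(allR[excluded]) <= 0.6))
  # ordering: block kind (GF, FD, GFA) then wavelength
  expect_equal(info$kind, info$kind[order(match(info$kind, c("GF", "FD", "GFA")))])
  for (k in unique(info$kind))
    expect_false(is.unsorted(info$wavelength[info$kind == k]))
  # determinism
  fs2 <- selectFeatures(list(GFA = gfa, FD = fd, GF = gf), y, 0.6)
  expect_identical(featureInfo(fs2), info)
})

test_that("a six-feature characteristic set arises from 2 GF + 4 GFA", {
  set.seed(13)
  n <- 40
  y <- rnorm(n)
  weak <- function() 0.2 * y + rnorm(n)     # |rho| well below 0.6
  gf <- mkBlock("GF", c(486, 527, 740), list(-y + rnorm(n, 0, 0.2),
                                             -y + rnorm(n, 0, 0.25), weak()), n)
  fd <- mkBlock("FD", c(769, 849), list(weak(), weak()), n)
  gfa <- mkBlock("GFA", c(769, 1033, 1147, 2336, 2000),
                 list(-y^3, exp(y), y + rnorm(n, 0, 0.1),
                      -y + rnorm(n, 0, 0.15), weak()), n)
  fs <- selectFeatures(list(GF = gf, FD = fd, GFA = gfa), y, 0.6)
  expect_equal(ncol(featureValues(fs)), 6L)
  expect_equal(unname(table(featureInfo(fs)$kind)["GF"]), 2L)
  expect_equal(unname(table(featureInfo(fs)$kind)["GFA"]), 4L)
})

test_that("an unattainable threshold yields an explicit empty result", {
  set.seed(14)
  n <- 30
  y <- rnorm(n)
  gf <- mkBlock("GF", c(500, 600), list(rnorm(n), rnorm(n)), n)
  expect_message(fs <- selectFeatures(list(GF = gf), y, threshold = 1),
                 "empty")
  expect_equal(ncol(featureValues(fs)), 0L)
  # saturation: every feature a monotone copy of y
  gf2 <- mkBlock("GF", c(500, 600), list(rank(y), exp(y)), n)
  fs2 <- selectFeatures(list(GF = gf2), y, 0.6)
  expect_equal(featureInfo(fs2)$spearman_r, c(1, 1))
})
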