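# build a PopulationHeatmap directly from a fraction matrix
heatmapFrom <- function(fr, g, biomarker = "SRF", n = 10L) {
  new("PopulationHeatmap", fraction = fr, nEyes = as.integer(n),
      biomarker = biomarker, geometry = g)
}

# heatmap sampled exactly from the isotropic Gaussian model
gaussianHeatmap <- function(g, A, muX, muY, sigma) {
  fr <- outer(bscanPositionsUm(g), ascanPositionsUm(g),
              function(y, x) gaussian2d(x, y, A, muX, muY, sigma))
  heatmapFrom(fr, g)
}

test_that("aggregation averages presence maps over eyes", {
  g <- smallGeometry()
  m1 <- enfaceMap(volumeWithVoxels(cbind(2L, 10L, 3L), 3L, g), "SRF")
  m2 <- enfaceMap(volumeWithVoxels(cbind(7L, 10L, 40L), 3L, g), "SRF")
  h1 <- aggregateHeatmap(list(m1))
  expect_identical(h1@fraction, m1@presence + 0)
  h <- aggregateHeatmap(list(m1, m2))
  expect_equal(h@nEyes, 2L)
  expect_equal(h@fraction[3L, 4L], 0.5)
  expect_equal(h@fraction[8L, 41L], 0.5)
  expect_equal(sum(h@fraction), 1)
  # all eyes positive at one pixel -> fraction 1 there
  hh <- aggregateHeatmap(list(m1, m1, m1))
  expect_equal(hh@fraction[3L, 4L], 1)
  expect_error(aggregateHeatmap(list()), "empty")
  m3 <- enfaceMap(volumeWithVoxels(cbind(2L, 10L, 3L), 2L, g), "IRF")
  expect_error(aggregateHeatmap(list(m1, m3)), "mixed biomarkers")
  m4 <- enfaceMap(emptyVolume(scanGeometryNew()), "SRF")
  expect_error(aggregateHeatmap(list(m1, m4)), "mixed geometries")
})

test_that("the Gaussian surface evaluates its closed forms", {
  expect_equal(gaussian2d(1200, 3400, 0.9, 1200, 3400, 800), 0.9)
  # at squared radius 2 sigma^2 the surface is A / e
  s <- 700
  expect_equal(gaussian2d(s * sqrt(2), 0, 0.5, 0, 0, s), 0.5 * exp(-1))
  expect_equal(gaussian2d(-1000, 2000, 0, 500, 500, 300), 0)
  expect_error(gaussian2d(0, 0, 1, 0, 0, 0), "sigma")
  expect_error(gaussian2d(0, 0, 1, 0, 0, -5), "sigma")
})

test_that("a realizable heatmap is recovered to numerical precision", {
  h <- gaussianHeatmap(scanGeometryNew(), 0.9, 3000, 3000, 800)
  fit <- fitGaussian(h)
  expect_true(fit@converged)
  expect_lt(abs(fit@amplitude - 0.9) / 0.9, 1e-6)
  expect_lt(abs(fit@muX - 3000) / 3000, 1e-6)
  expect_lt(abs(fit@muY - 3000) / 3000, 1e-6)
  expect_lt(abs(fit@sigma - 800) / 800, 1e-6)
  expect_gte(fit@rSquared, 0.999999)
})

test_that("shifting a heatmap shifts the fitted center equivariantly", {
  g <- scanGeometryNew()
  base <- gaussianHeatmap(g, 0.8, 2500, 2750, 500)
  fr <- base@fraction
  # shift by 2 B-scans (+250 um in y) and 20 A-scans (+250 um in x);
  # sigma = 500 um keeps the mass far from the borders
  sh <- matrix(0, nrow(fr), ncol(fr))
  sh[3:nrow(fr), 21:ncol(fr)] <- fr[1:(nrow(fr) - 2), 1:(ncol(fr) - 20)]
  f0 <- fitGaussian(base)
  f1 <- fitGaussian(heatmapFrom(sh, g))
  expect_equal(f1@muX - f0@muX, 250, tolerance = 1e-3)
  expect_equal(f1@muY - f0@muY, 250, tolerance = 1e-3)
  expect_equal(f1@sigma, f0@sigma, tolerance = 1e-4)
  expect_equal(f1@amplitude, f0@amplitude, tolerance = 1e-4)
})

test_that("degenerate heatmaps are flagged rather than fitted", {
  g <- smallGeometry()
  zero <- heatmapFrom(matrix(0, g@nBscans, g@nAscans), g)
  expect_error(fitGaussian(zero), "zero heatmap")
  const <- heatmapFrom(matrix(0.4, g@nBscans, g@nAscans), g)
  fit <- fitGaussian(const)
  expect_false(fit@converged)
  expect_true(is.nan(fit@rSquared))
})

test_that("pixel noise lowers the coefficient of determination", {
  g <- scanGeometryNew()
  clean <- gaussianHeatmap(g, 0.8, 3000, 3000, 800)
  r2 <- vapply(c(0.01, 0.05), function(sd) {
    set.seed(99)
    noisy <- pmin(pmax(clean@fraction +
                         matrix(rnorm(length(clean@fraction), 0, sd),
                                nrow(clean@fraction)), 0), 1)
    fitGaussian(heatmapFrom(noisy, g))@rSquared
  }, numeric(1L))
  expect_lt(r2[1L], 1)
  expect_lt(r2[2L], r2[1L])
})

test_that("fitted spread agrees with the moment estimator on a lesion cohort", {
  # single small lesion per positive eye, tight size range: the population
  # heatmap is then close to the generating center-distribution
  preset <- diseasePreset("AMD", c(IRF = 0.25, SRF = 0.55, PED = 0.90),
                          lesionCountMean = 0,
                          lesionRadiusRange = c(150, 300))
  cfg <- smallAmdConfig(200L, seed = 11L, preset = preset)
  maps <- lapply(seq_len(200L), function(i)
    enfaceMap(mirrorIfLeft(sampleEye(cfg, i)), "PED"))
  h <- aggregateHeatmap(maps)
  fit <- fitGaussian(h)
  expect_true(fit@converged)
  # moment oracle computed inline, independent of the optimizer
  fr <- h@fraction
  x <- ascanPositionsUm(h@geometry)[col(fr)]
  y <- bscanPositionsUm(h@geometry)[row(fr)]
  w <- as.vector(fr)
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sg <- sqrt(sum(w * ((x - mx)^2 + (y - my)^2)) / (2 * sum(w)))
  expect_lt(abs(fit@sigma - sg) / sg, 0.20)
  mom <- heatmapMoments(h)
  expect_equal(mom$sigma, sg)
  expect_equal(mom$muX, mx)
})
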