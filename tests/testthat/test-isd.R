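test_that("decimation halves the sampling and keeps both borders", {
  cfg <- cohortConfig(1L, amdPreset(), seed = 3L)   # default 49-scan grid
  v <- sampleEye(cfg, 1L)
  d2 <- decimate(v, 2L)
  expect_equal(d2@geometry@nBscans, 25L)
  expect_equal(isdUm(d2@geometry), 250)
  expect_identical(d2@labels[1L, , ], v@labels[1L, , ])
  expect_identical(d2@labels[25L, , ], v@labels[49L, , ])
  expect_identical(d2@labels[2L, , ], v@labels[3L, , ])

  expect_identical(decimate(v, 1L), v)

  d8 <- decimate(v, 8L)
  expect_equal(d8@geometry@nBscans, 7L)
  expect_equal(isdUm(d8@geometry), 1000)
  expect_identical(d8@labels[1L, , ], v@labels[1L, , ])
  expect_identical(d8@labels[7L, , ], v@labels[49L, , ])

  expect_error(decimate(v, 3L), "power of two")
  expect_error(decimate(v, 32L), "does not divide")
})

test_that("border-corrected weights always sum to the slow-axis extent", {
  for (f in c(1L, 2L, 4L, 8L)) {
    g <- scanGeometryNew(isd = 125 * f, nBscans = (49L - 1L) / f + 1L)
    w <- scanWeights(g)
    expect_identical(sum(w), 6000)
    expect_identical(w[1L], w[length(w)])
    expect_identical(w[1L], 125 * f / 2)
  }
})

test_that("volume estimation is exact on uniform slabs", {
  g <- scanGeometryNew()
  expect_identical(estimateVolume(emptyVolume(g), "IRF"), 0)
  slab <- slabVolume(g, thickVox = 43L)   # 43 * 7 = 301 um thick
  v <- estimateVolume(slab, "retina")
  expect_equal(v, 6000 * 6000 * 301)
  # constant cross-section: decimation cannot change the estimate
  for (f in c(2L, 4L, 8L))
    expect_identical(estimateVolume(decimate(slab, f), "retina"), v)
  expect_identical(totalRetinaVolume(slab), v)
})

test_that("a lesion on an odd B-scan disappears at the first decimation", {
  g <- scanGeometryNew()
  v <- volumeWithVoxels(cbind(1L, 200L, 100L), 2L, g)   # B-scan index 1
  s <- sensitivityByIsd(list(v), "IRF", factors = c(1L, 2L))
  expect_equal(unname(s), c(1, 0))
  expect_true(biomarkerPresent(v, "IRF"))
  expect_false(biomarkerPresent(decimate(v, 2L), "IRF"))
})

test_that("MAPE matches hand-computed cases and its invariances", {
  expect_equal(as.numeric(mape(100, 90)), 10)
  expect_equal(as.numeric(mape(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(mape(c(100, 200), c(110, 150))), 17.5)
  # scale invariance
  expect_equal(as.numeric(mape(c(100, 200) * 3.7, c(110, 150) * 3.7)), 17.5)
  # zero-reference pairs are excluded from the sum and from n
  m <- mape(c(0, 100), c(5, 90))
  expect_equal(as.numeric(m), 10)
  expect_equal(attr(m, "n"), 1L)
  expect_equal(attr(m, "nExcluded"), 1L)
  expect_error(mape(c(0, 0), c(1, 2)), "undefined")
  expect_error(mape(1:3, 1:2), "paired")
})

test_that("ISD sensitivities and volumes match the brute-force oracle", {
  cfg <- smallAmdConfig(10L, seed = 5L)
  vols <- lapply(seq_len(10L), function(i) mirrorIfLeft(sampleEye(cfg, i)))
  for (b in c("SRF", "PED")) {
    s <- sensitivityByIsd(vols, b)
    refPos <- vapply(vols, function(v)
      oracleIsdEye(v, b, 1L)$present, logical(1L))
    for (k in seq_along(c(1L, 2L, 4L, 8L))) {
      f <- c(1L, 2L, 4L, 8L)[k]
      hits <- vapply(vols[refPos], function(v)
        oracleIsdEye(v, b, f)$present, logical(1L))
      expect_identical(unname(s[k]), mean(hits))
    }
  }
  vdf <- volumesByIsd(vols, biomarkers = c("IRF", "retina"))
  for (r in seq_len(nrow(vdf))) {
    o <- oracleIsdEye(vols[[match(vdf$eyeId[r],
                                  vapply(vols, eyeId, ""))]],
                      vdf$biomarker[r], vdf$factor[r])
    expect_identical(vdf$volumeUm3[r], o$volume)
  }
})

test_that("a cohort with no positive eyes yields n/a MAPE, not an error", {
  g <- smallGeometry()
  vols <- lapply(1:3, function(i) emptyVolume(g, eyeId = paste0("e", i)))
  expect_error(sensitivityByIsd(vols, "PED"), "no reference-positive")
  vdf <- volumesByIsd(vols, biomarkers = c("PED", "retina"))
  expect_true(all(vdf$volumeUm3[vdf$biomarker == "PED"] == 0))
  mt <- mapeTable(vdf)
  expect_true(all(is.na(mt$PED)))
  expect_true(all(is.na(mt$retina)))   # empty volumes have no retina either
})

test_that("generator functions stream eyes without materializing the cohort", {
  cfg <- smallAmdConfig(6L, seed = 29L)
  gen <- function(i) mirrorIfLeft(sampleEye(cfg, i))
  vols <- lapply(1:6, gen)
  expect_identical(sensitivityByIsd(gen, "SRF", nEyes = 6L),
                   sensitivityByIsd(vols, "SRF"))
  expect_identical(volumesByIsd(gen, biomarkers = "SRF", nEyes = 6L),
                   volumesByIsd(vols, biomarkers = "SRF"))
})
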