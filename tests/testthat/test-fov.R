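test_that("crop presence respects closed-rectangle geometry", {
  g <- scanGeometryNew()
  # lesion at physical (5000, 5000): x index 400 (400 * 12.5), y index 40
  v <- volumeWithVoxels(cbind(40L, 100L, 400L), 2L, g)
  m <- enfaceMap(v, "IRF")
  expect_true(cropPresence(m, cropWindow(6000, 6000)))   # full FOV
  expect_false(cropPresence(m, cropWindow(2000, 2000)))  # centered 2x2 mm
  # zero-measure window exactly on the lesion: closed interval includes it
  expect_true(cropPresence(m, cropWindow(0.0001, 0.0001,
                                         centerX = 5000, centerY = 5000)))
  expect_false(cropPresence(enfaceMap(emptyVolume(g), "IRF"),
                            cropWindow(6000, 6000)))
  expect_error(cropPresence(m, cropWindow(2000, 2000, centerX = 5500)),
               "outside")
})

test_that("full-FOV crop equals plain presence on sampled eyes", {
  cfg <- smallAmdConfig(4L, seed = 13L)
  for (i in 1:4) {
    m <- enfaceMap(mirrorIfLeft(sampleEye(cfg, i)), "SRF")
    expect_identical(cropPresence(m, cropWindow(6000, 6000)),
                     any(m@presence == 1L))
  }
})

test_that("the sensitivity map is 1 at full size and for foveal lesions", {
  g <- smallGeometry()
  # every lesion touches the exact FOV center pixel
  ctr <- volumeWithVoxels(cbind(12L, 30L, 48L), 3L, g)  # (3000, 3000) um
  maps <- list(enfaceMap(ctr, "SRF"), enfaceMap(ctr, "SRF"))
  sm <- sensitivityMap(maps)
  expect_true(all(sm@sensitivity == 1))
  expect_equal(sm@nPositiveReference, 2L)
  # off-center cohort: full-size entry still exactly 1
  off <- enfaceMap(volumeWithVoxels(cbind(24L, 30L, 90L), 3L, g), "SRF")
  sm2 <- sensitivityMap(list(off))
  s <- sensitivity(sm2)
  expect_equal(s[nrow(s), ncol(s)], 1.0)
  expect_lt(s[1L, 1L], 1.0)
})

test_that("reference-negative eyes never affect the map", {
  cfg <- smallAmdConfig(12L, seed = 17L)
  maps <- lapply(seq_len(12L), function(i)
    enfaceMap(mirrorIfLeft(sampleEye(cfg, i)), "SRF"))
  sm <- sensitivityMap(maps)
  g <- smallGeometry()
  negatives <- lapply(1:10, function(i) enfaceMap(emptyVolume(g), "SRF"))
  sm2 <- sensitivityMap(c(maps, negatives))
  expect_identical(sm@sensitivity, sm2@sensitivity)
  expect_identical(sm@nPositiveReference, sm2@nPositiveReference)
  # a cohort with no positive eye at all is an explicit error
  expect_error(sensitivityMap(negatives), "no reference-positive eyes")
})

test_that("the optimized map matches the brute-force oracle on a small cohort", {
  cfg <- smallAmdConfig(8L, seed = 19L)
  maps <- lapply(seq_len(8L), function(i)
    enfaceMap(mirrorIfLeft(sampleEye(cfg, i)), "IRF_SRF"))
  sm <- sensitivityMap(maps)
  expect_identical(sm@sensitivity, oracleSensitivityMap(maps))
})

test_that("exemplary sensitivities pick the highlighted crop sizes", {
  g <- smallGeometry()
  ctr <- volumeWithVoxels(cbind(12L, 30L, 48L), 3L, g)
  sm <- sensitivityMap(list(enfaceMap(ctr, "SRF")))
  ex <- exemplarySensitivities(sm)
  expect_identical(ex$fov, c("full", "3x3 mm", "2x2 mm", "1x1 mm"))
  expect_equal(ex$sensitivity, c(1, 1, 1, 1))
  # nested crops force monotone exemplary values
  cfg <- smallAmdConfig(30L, seed = 23L)
  maps <- lapply(seq_len(30L), function(i)
    enfaceMap(mirrorIfLeft(sampleEye(cfg, i)), "SRF"))
  ex2 <- exemplarySensitivities(sensitivityMap(maps))
  v <- ex2$sensitivity
  expect_true(v[1L] >= v[2L] && v[2L] >= v[3L] && v[3L] >= v[4L])
})
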