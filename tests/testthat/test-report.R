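cohortDir <- function(nEyes, preset, seed, dir) {
  cfg <- cohortConfig(nEyes, preset, geometry = smallGeometry(), seed = seed)
  sampleCohort(cfg, dir)
  file.path(dir, "manifest.csv")
}

test_that("the full pipeline emits every section with consistent bookkeeping", {
  d <- withr::local_tempdir()
  mf <- cohortDir(12L, amdPreset(), 7L, d)
  out <- file.path(d, "out")
  bundle <- runAll(runConfig(mf, outDir = out, logLevel = "quiet"))
  s <- bundle$summary

  expect_named(s, c("nEyes", "geometry", "prevalence", "heatmapFit", "fov",
                    "isd"))
  expect_equal(s$nEyes, 12L)
  expect_setequal(names(s$prevalence), c("IRF", "SRF", "IRF_SRF", "PED"))
  for (b in names(s$prevalence)) {
    p <- s$prevalence[[b]]
    expect_equal(p$nEyes, 12L)
    expect_equal(p$percent, 100 * p$nPositive / 12)
    # prevalence agrees with an independent recount from the manifest
    m <- readManifest(mf)
    k <- sum(vapply(m$path, function(pp)
      biomarkerPresent(readVolume(pp), b), logical(1L)))
    expect_equal(p$nPositive, k)
  }
  # pooled IRF_SRF is at least as prevalent as each component
  expect_gte(s$prevalence$IRF_SRF$nPositive, s$prevalence$IRF$nPositive)
  expect_gte(s$prevalence$IRF_SRF$nPositive, s$prevalence$SRF$nPositive)

  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "volumes.csv")))
  expect_true(file.exists(file.path(out, "mape.csv")))

  # composition equals stage-by-stage invocation
  vols <- lapply(readManifest(mf)$path,
                 function(p) mirrorIfLeft(readVolume(p)))
  maps <- lapply(vols, enfaceMap, biomarker = "SRF")
  expect_equal(bundle$heatmaps$SRF@fraction,
               aggregateHeatmap(maps)@fraction)
  expect_identical(bundle$fovMaps$SRF@sensitivity,
                   sensitivityMap(maps)@sensitivity)
  expect_equal(unname(unlist(s$isd$sensitivity$SRF)),
               unname(sensitivityByIsd(vols, "SRF")))
})

test_that("reruns on identical inputs are byte-identical", {
  d <- withr::local_tempdir()
  mf <- cohortDir(5L, amdPreset(), 13L, d)
  o1 <- file.path(d, "o1"); o2 <- file.path(d, "o2")
  runAll(runConfig(mf, outDir = o1, logLevel = "quiet"))
  runAll(runConfig(mf, outDir = o2, logLevel = "quiet"))
  expect_identical(readLines(file.path(o1, "summary.json")),
                   readLines(file.path(o2, "summary.json")))
})

test_that("biomarkers absent from a cohort are reported n/a", {
  d <- withr::local_tempdir()
  mf <- cohortDir(8L, rvoPreset(), 5L, d)
  bundle <- runAll(runConfig(mf, logLevel = "quiet"))
  s <- bundle$summary
  expect_identical(s$heatmapFit$PED, "n/a")
  expect_identical(s$fov$PED, "n/a")
  expect_identical(s$isd$sensitivity$PED, "n/a")
  expect_true(all(unlist(s$isd$mape$PED) == "n/a"))
  # IRF is universal in RVO
  expect_equal(s$prevalence$IRF$nPositive, 8L)
})

test_that("geometrically heterogeneous cohorts are refused with offenders", {
  d <- withr::local_tempdir()
  mf <- cohortDir(2L, amdPreset(), 3L, d)
  odd <- emptyVolume(scanGeometryNew(), eyeId = "odd_geo")
  writeVolume(odd, file.path(d, "odd.nii.gz"))
  m <- readManifest(mf)
  m <- rbind(m, data.frame(eye_id = "odd_geo",
                           path = file.path(d, "odd.nii.gz"),
                           laterality = "right", disease = "unknown"))
  mf2 <- file.path(d, "mixed.csv")
  writeManifest(m, mf2)
  expect_error(runAll(runConfig(mf2, logLevel = "quiet")),
               "odd_geo")
})

test_that("run configs load from YAML", {
  d <- withr::local_tempdir()
  yml <- file.path(d, "cfg.yaml")
  writeLines(c("manifest: m.csv", "biomarkers: [IRF, SRF]",
               "fov_step_um: 500", "isd_factors: [1, 2]", "seed: 4"), yml)
  cfg <- readRunConfig(yml)
  expect_equal(cfg$manifest, "m.csv")
  expect_equal(cfg$biomarkers, c("IRF", "SRF"))
  expect_equal(cfg$fovStepUm, 500)
  expect_equal(cfg$isdFactors, c(1L, 2L))
})

test_that("figures render for a small bundle", {
  d <- withr::local_tempdir()
  mf <- cohortDir(5L, amdPreset(), 17L, d)
  bundle <- runAll(runConfig(mf, biomarkers = c("SRF", "PED"),
                             logLevel = "quiet"))
  figs <- renderFigures(bundle, file.path(d, "figs"))
  expect_true(length(figs) >= 3)
  expect_true(all(file.exists(figs)))
})
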