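# Scene and cohort generators: determinism, planted-truth consistency,
# noise model, placement preconditions.

small_scene <- function(...) sceneParams(shape = c(10L, 96L, 96L),
                                         nMitoSegments = 3L, ...)

test_that("scene parameters validate their invariants", {
  expect_error(sceneParams(punctaRadius = 3, minSeparation = 4),
               "minSeparation")
  expect_error(sceneParams(nMitolysosomes = -1L), "counts")
  expect_error(sceneParams(shape = c(0L, 64L, 64L)), "shape")
  expect_error(sceneParams(noise = list(poissonScale = -1,
                                        gaussianSd = 0)), "noise")
})

test_that("reporter scenes are deterministic and symmetric without mitolysosomes", {
  p <- noiseFree(small_scene(nMitolysosomes = 0L,
                             channelGains = c(mCherry = 80, GFP = 40,
                                              DNA = 100, TOMM20 = 100,
                                              DAPI = 100)))
  sc <- generateReporterStack(p)
  mch <- getChannel(sc$stack, "mCherry")
  gfp <- getChannel(sc$stack, "GFP")
  # identical up to channel gains
  expect_equal(mch, 2 * gfp)
  expect_equal(nrow(truthObjects(sc$truth, "mitolysosome")), 0L)

  # bit-identical rerun
  sc2 <- generateReporterStack(p)
  expect_identical(sc$stack@data, sc2$stack@data)
  expect_identical(truthObjects(sc$truth), truthObjects(sc2$truth))

  # and noise does not move placement
  pn <- small_scene(nMitolysosomes = 12L, seed = 4L)
  t1 <- truthObjects(generateReporterStack(pn)$truth)
  t2 <- truthObjects(generateReporterStack(noiseFree(pn))$truth)
  expect_identical(t1, t2)
})

test_that("planted mitolysosomes are disjoint mCherry-only puncta recoverable at half peak", {
  p <- noiseFree(small_scene(nMitolysosomes = 15L, seed = 2L))
  sc <- generateReporterStack(p)
  mch <- getChannel(sc$stack, "mCherry")
  gfp <- getChannel(sc$stack, "GFP")
  tru <- truthObjects(sc$truth, "mitolysosome")
  expect_equal(nrow(tru), 15L)
  # voxel lookup at truth centres: mCherry at peak, GFP dark
  for (i in seq_len(nrow(tru))) {
    idx <- cbind(round(tru$y[i]), round(tru$x[i]), round(tru$z[i]))
    expect_gt(mch[idx], 50)
    expect_equal(gfp[idx], 0)
  }
  # truth consistency: half-peak thresholding of the mCherry-only
  # signal reproduces the planted count by brute-force components
  only <- (mch > 50) & !(gfp > 50)
  expect_equal(max(o_label3d(only, 26)), 15L)
  # pairwise separation honoured
  d <- as.matrix(stats::dist(tru[, c("y", "x", "z")]))
  diag(d) <- Inf
  expect_gte(min(d), p@minSeparation)
})

test_that("over-dense placement fails with a clear error", {
  expect_error(
    generateReporterStack(small_scene(nMitolysosomes = 300L,
                                      minSeparation = 30)),
    "min_separation")
})

test_that("noise model: per-voxel variance tracks the mean on flat signal", {
  p <- sceneParams(nMitolysosomes = 0L, nMitoSegments = 12L, seed = 6L)
  p0 <- noiseFree(p)
  clean <- getChannel(generateReporterStack(p0)$stack, "GFP")
  noisy <- getChannel(generateReporterStack(p)$stack, "GFP")
  flat <- which(clean == 120)          # network interior, constant level
  expect_gt(length(flat), 1e4)
  want <- 120 / p@noise$poissonScale + p@noise$gaussianSd^2
  expect_equal(stats::var(noisy[flat]), want, tolerance = 0.2)
  # dark background region has only the additive component
  dark <- which(clean == 0)
  v_dark <- stats::var(noisy[dark])
  expect_lt(v_dark, want / 2)
})

test_that("DNA scenes plant cytosolic foci outside organelles, per cell", {
  p <- noiseFree(sceneParams(seed = 3L, nCytoDnaFoci = 8L))
  sc <- generateDnaStack(p)
  tru <- truthObjects(sc$truth, "cyto_dna_focus")
  expect_equal(nrow(tru), 8L)
  tom <- getChannel(sc$stack, "TOMM20")
  dap <- getChannel(sc$stack, "DAPI")
  for (i in seq_len(nrow(tru))) {
    idx <- cbind(round(tru$y[i]), round(tru$x[i]), round(tru$z[i]))
    expect_equal(tom[idx], 0)
    expect_equal(dap[idx], 0)
  }
  # nucleoids sit inside the rendered network
  nl <- truthObjects(sc$truth, "mito_nucleoid")
  for (i in seq_len(nrow(nl)))
    expect_gt(tom[cbind(nl$y[i], nl$x[i], nl$z[i])], 0)
  # ROIs tile the field and label the foci
  rois <- cellRois(sc$truth)
  expect_true(all(rois >= 1))
  expect_equal(tru$cell,
               rois[cbind(round(tru$y), round(tru$x))])
  # determinism
  sc2 <- generateDnaStack(p)
  expect_identical(sc$stack@data, sc2$stack@data)
})

test_that("fociCell confines every planted focus to the requested ROI", {
  p <- noiseFree(sceneParams(seed = 8L, nCytoDnaFoci = 8L,
                             fociCell = 2L))
  sc <- generateDnaStack(p)
  tru <- truthObjects(sc$truth, "cyto_dna_focus")
  expect_equal(nrow(tru), 8L)
  expect_true(all(tru$cell == 2L))
})

test_that("qPCR cohorts invert exactly in the noise-free limit", {
  cp <- cohortParams(nPerGroup = 4L, foldChange = 10, ctNoiseSd = 0,
                     seed = 5L)
  rec <- generateQpcrCohort(cp)
  expect_true(all(table(rec$sample_id) == 1 + 2 * 3))
  # cytosolic Ct sits exactly log2(10) below the mitochondrial Ct
  for (g in cp$genes) {
    old_c <- rec$ct[rec$group == "old" & rec$gene == g &
                      rec$fraction == "cytosolic"]
    old_m <- rec$ct[rec$group == "old" & rec$gene == g &
                      rec$fraction == "mitochondrial"]
    expect_equal(old_m - old_c, rep(log2(10), 4))
    yng_c <- rec$ct[rec$group == "young" & rec$gene == g &
                      rec$fraction == "cytosolic"]
    yng_m <- rec$ct[rec$group == "young" & rec$gene == g &
                      rec$fraction == "mitochondrial"]
    expect_equal(yng_c, yng_m)
  }
  # empty cohort
  expect_equal(nrow(generateQpcrCohort(cohortParams(nPerGroup = 0L))),
               0L)
  # determinism
  expect_identical(rec, generateQpcrCohort(cp))
})

test_that("measurement cohorts shift location as configured and rerun identically", {
  tb <- generateMeasurementCohort(10, effectSize = 3,
                                  distribution = "normal", seed = 7)
  expect_identical(tb, generateMeasurementCohort(10, 3, "normal", 7))
  expect_equal(nrow(tb), 20L)
  # across many seeds the group difference averages the configured shift
  diffs <- vapply(1:60, function(s) {
    t2 <- generateMeasurementCohort(12, 2, "normal", s)
    mean(t2$value[t2$group == "g2"]) - mean(t2$value[t2$group == "g1"])
  }, 0)
  expect_equal(mean(diffs), 2, tolerance = 0.15)
  # lognormal data fails normality screening at moderate n
  ln <- generateMeasurementCohort(40, 0, "lognormal", 9)
  fl <- assessAssumptions(ln$value, ln$group)
  expect_true(all(!fl$normal))
  expect_error(generateMeasurementCohort(1, 0, "normal", 1))
})
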