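# Quantification procedures against simulator ground truth. Scenes are
# kept at 96x96x10 voxels here so the whole file stays fast; the
# acceptance tests exercise the full-size default scenes.

q_scene <- function(...) sceneParams(shape = c(10L, 96L, 96L),
                                     nMitoSegments = 3L, ...)

grid_centers <- function(k) {
  g <- expand.grid(y = c(12, 30, 48), x = c(12, 30, 48))
  cbind(g$y[seq_len(k)], g$x[seq_len(k)], rep(c(3L, 4L), length.out = k))
}

spot_stack <- function(centers, shape = c(64L, 64L, 6L), amp = 100,
                       channels = c("LC3", "LAMP1"),
                       on = list()) {
  vol0 <- array(0, shape)
  spot_at <- function(vol, c3) {
    for (y in -4:4) for (x in -4:4) for (z in -2:2) {
      d2 <- y^2 + x^2 + z^2
      if (d2 <= 20.25) {
        iy <- c3[1] + y; ix <- c3[2] + x; iz <- c3[3] + z
        if (iy >= 1 && iy <= shape[1] && ix >= 1 && ix <= shape[2] &&
            iz >= 1 && iz <= shape[3])
          vol[iy, ix, iz] <- vol[iy, ix, iz] +
            amp * exp(-d2 / (2 * 1.5^2))
      }
    }
    vol
  }
  chans <- list()
  for (ch in channels) {
    v <- vol0
    sel <- if (length(on)) on[[ch]] else seq_len(nrow(centers))
    for (i in sel) v <- spot_at(v, centers[i, ])
    chans[[ch]] <- v
  }
  ImageStack(chans, voxelSize = c(0.5, 0.2, 0.2))
}

test_that("mitolysosome counting recovers planted counts and masses", {
  p <- noiseFree(q_scene(nMitolysosomes = 12L, seed = 11L))
  sc <- generateReporterStack(p)
  thr <- freezeThresholds(sc$stack, c("mCherry", "GFP"), 25, 1)
  res <- countMitolysosomes(sc$stack, thr)
  expect_equal(metrics(res)$n_mitolysosomes, 12L)

  # mitochondrial mass within 5% of the rendered network volume when
  # the batch threshold is fixed at half the network intensity (the
  # half-maximum cut that preserves volume under blurring)
  seg <- truthObjects(sc$truth, "mitochondrion_segment")
  rendered_um3 <- seg$extent[1] * prod(voxelSize(sc$stack))
  res_half <- countMitolysosomes(sc$stack, c(mCherry = 60, GFP = 60))
  expect_equal(metrics(res_half)$mitochondrial_mass_um3, rendered_um3,
               tolerance = 0.05)

  # empty scene
  p0 <- noiseFree(q_scene(nMitolysosomes = 0L, seed = 11L))
  sc0 <- generateReporterStack(p0)
  expect_equal(metrics(countMitolysosomes(sc0$stack, thr))$n_mitolysosomes,
               0L)

  # the mitolysosome mask is disjoint from the GFP mask by construction
  expect_true(all(c("radius", "sigma", "thresholds", "connectivity")
                  %in% names(paramsEcho(res))))
  expect_error(countMitolysosomes(sc$stack, c(mCherry = 50)),
               "unset batch threshold")
  bad <- ImageStack(list(mCherry = array(0, c(4, 4, 2))))
  expect_error(countMitolysosomes(bad, thr), "missing channel")
})

test_that("a background ramp up to half the spot peak changes no count", {
  for (s in c(12L, 13L)) {
    p_flat <- noiseFree(q_scene(nMitolysosomes = 10L, seed = s))
    p_ramp <- p_flat
    p_ramp@backgroundAmplitude <- 50
    sc_f <- generateReporterStack(p_flat)
    sc_r <- generateReporterStack(p_ramp)
    thr <- freezeThresholds(sc_f$stack, c("mCherry", "GFP"), 25, 1)
    expect_equal(
      metrics(countMitolysosomes(sc_r$stack, thr))$n_mitolysosomes,
      metrics(countMitolysosomes(sc_f$stack, thr))$n_mitolysosomes)
  }
})

test_that("recovered counts never decrease when more puncta are planted", {
  thr <- NULL
  last <- -1L
  for (n in c(5L, 10L, 20L)) {
    sc <- generateReporterStack(noiseFree(q_scene(nMitolysosomes = n,
                                                  seed = 14L)))
    if (is.null(thr))
      thr <- freezeThresholds(sc$stack, c("mCherry", "GFP"), 25, 1)
    cnt <- metrics(countMitolysosomes(sc$stack, thr))$n_mitolysosomes
    expect_gte(cnt, last)
    last <- cnt
  }
})

test_that("autophagy structure counting handles single and double positives", {
  centers <- grid_centers(6)
  # identical supports: every LC3 punctum is double positive
  st_same <- spot_stack(centers)
  thr <- c(LC3 = 30, LAMP1 = 30)
  r1 <- countAutophagyStructures(st_same, thr)
  expect_equal(metrics(r1)$n_LC3, 6L)
  expect_equal(metrics(r1)$n_LC3_LAMP1, metrics(r1)$n_LC3)

  # disjoint supports: no double positives
  st_disj <- spot_stack(centers, on = list(LC3 = 1:3, LAMP1 = 4:6))
  r2 <- countAutophagyStructures(st_disj, thr)
  expect_equal(metrics(r2)$n_LC3, 3L)
  expect_equal(metrics(r2)$n_LAMP1, 3L)
  expect_equal(metrics(r2)$n_LC3_LAMP1, 0L)

  # k planted double positives among singles
  st_k <- spot_stack(centers, on = list(LC3 = 1:5, LAMP1 = 3:6))
  r3 <- countAutophagyStructures(st_k, thr)
  expect_equal(metrics(r3)$n_LC3_LAMP1, 3L)
})

test_that("pUb quantification: per-cell MFI scales with signal; tissue area fraction", {
  centers <- grid_centers(5)
  rois <- matrix(1L, 64, 64)
  rois[, 33:64] <- 2L
  st <- spot_stack(centers, channels = "pUb")
  r <- quantifyPUb(st, "cell_mfi", cellRois = rois)
  expect_equal(nrow(perCell(r)), 2L)

  st2 <- spot_stack(centers, channels = "pUb", amp = 200)
  r2 <- quantifyPUb(st2, "cell_mfi", cellRois = rois)
  expect_equal(perCell(r2)$mfi, 2 * perCell(r)$mfi, tolerance = 0.02)

  rt <- quantifyPUb(st, "tissue_area", threshold = 30)
  proj <- maxProject(medianDespeckle(rollingBallSubtract(
    getChannel(st, "pUb"), 25)))
  expect_true(metrics(rt)$area_fraction > 0 &&
                metrics(rt)$area_fraction < 0.5)
  zero <- ImageStack(list(pUb = array(0, c(32, 32, 2))))
  expect_equal(metrics(quantifyPUb(zero, "cell_mfi",
                                   cellRois = matrix(1L, 32, 32)))$mfi,
               0)
  expect_equal(metrics(quantifyPUb(zero, "tissue_area",
                                   threshold = 10))$area_fraction, 0)
  expect_error(quantifyPUb(st, "cell_mfi"), "cellRois")
})

test_that("cytosolic DNA foci: exact per-cell recovery and exclusion completeness", {
  p <- noiseFree(sceneParams(seed = 5L))
  sc <- generateDnaStack(p)
  thr <- freezeThresholds(sc$stack, c("TOMM20", "DAPI"), 25, 0.75)
  res <- countCytosolicDnaFoci(sc$stack, cellRois(sc$truth), thr)
  tru <- truthObjects(sc$truth, "cyto_dna_focus")
  want <- as.integer(table(factor(tru$cell,
                                  levels = perCell(res)$cell)))
  expect_equal(perCell(res)$n_foci, want)
  expect_equal(metrics(res)$n_foci_total, nrow(tru))

  # nucleoids only inside organelles: every cell scores 0
  p0 <- noiseFree(sceneParams(seed = 5L, nCytoDnaFoci = 0L))
  sc0 <- generateDnaStack(p0)
  res0 <- countCytosolicDnaFoci(sc0$stack, cellRois(sc0$truth), thr)
  expect_true(all(perCell(res0)$n_foci == 0L))

  # per-cell counts sum to the whole-field count when ROIs tile
  whole <- matrix(1L, nrow(cellRois(sc$truth)),
                  ncol(cellRois(sc$truth)))
  resw <- countCytosolicDnaFoci(sc$stack, whole, thr)
  expect_equal(metrics(resw)$n_foci_total, metrics(res)$n_foci_total)

  expect_error(countCytosolicDnaFoci(sc$stack,
                                     matrix(0L, 256, 256), thr),
               "empty ROI")
})

test_that("4-HNE aggregates: planted recovery and offset invariance", {
  centers <- grid_centers(7)
  st <- spot_stack(centers, channels = "HNE")
  thr <- c(HNE = 30)
  r <- countHneAggregates(st, thr)
  expect_equal(metrics(r)$n_aggregates, 7L)

  # constant offsets are background; rolling ball removes them
  st_off <- ImageStack(list(HNE = getChannel(st, "HNE") + 20),
                       voxelSize = voxelSize(st))
  r2 <- countHneAggregates(st_off, thr)
  expect_equal(metrics(r2)$n_aggregates, 7L)

  empty <- ImageStack(list(HNE = array(0, c(32, 32, 4))))
  expect_equal(metrics(countHneAggregates(empty, thr))$n_aggregates,
               0L)
  expect_error(countHneAggregates(st, c(DNA = 1)), "unset batch")
})

test_that("cGAS-DNA overlap follows the Manders definition on masks", {
  centers <- grid_centers(6)
  thr <- c(cGAS = 30, DNA = 30)
  st_same <- spot_stack(centers, channels = c("cGAS", "DNA"))
  expect_equal(metrics(cgasDnaOverlap(st_same, thr))$overlap_coefficient,
               1, tolerance = 1e-9)

  st_disj <- spot_stack(centers, channels = c("cGAS", "DNA"),
                        on = list(cGAS = 1:3, DNA = 4:6))
  expect_equal(metrics(cgasDnaOverlap(st_disj, thr))$overlap_coefficient,
               0, tolerance = 1e-9)

  # half-overlapping supports equal the direct-sum oracle
  st_half <- spot_stack(centers, channels = c("cGAS", "DNA"),
                        on = list(cGAS = 1:4, DNA = 3:6))
  got <- metrics(cgasDnaOverlap(st_half, thr))$overlap_coefficient
  cg <- gaussianBlur(rollingBallSubtract(getChannel(st_half, "cGAS"),
                                         20), 0.75)
  dn <- gaussianBlur(rollingBallSubtract(getChannel(st_half, "DNA"),
                                         20), 0.75)
  sel <- as.vector(cg > 30 | dn > 30)
  expect_equal(got, o_overlap(cg, dn, sel))
})

test_that("cardiolipin and marker MFIs behave on constructed scenes", {
  const <- ImageStack(list(NAO = array(4, c(16, 16, 3)),
                           TOMM20 = array(2, c(16, 16, 3))))
  r <- cardiolipinQuant(const)
  expect_equal(metrics(r)$nao_mfi, 4)
  expect_equal(metrics(r)$overlap_coefficient, 1)

  centers <- grid_centers(5)
  stc <- spot_stack(centers, channels = c("NAO", "TOMM20"))
  expect_gte(metrics(cardiolipinQuant(stc))$overlap_coefficient, 0.99)
  std <- spot_stack(centers, channels = c("NAO", "TOMM20"),
                    on = list(NAO = 1:2, TOMM20 = 3:5))
  expect_equal(metrics(cardiolipinQuant(std))$overlap_coefficient, 0,
               tolerance = 1e-9)
  expect_equal(metrics(markerMfi(const, "NAO"))$mfi, 4)
})

test_that("batch runs are deterministic, fault-tolerant and match single calls", {
  tmp <- withr::local_tempdir()
  paths <- character(0)
  singles <- integer(0)
  thr <- NULL
  for (s in 1:3) {
    sc <- generateReporterStack(noiseFree(q_scene(nMitolysosomes = 4L + s,
                                                  seed = 20L + s)))
    if (is.null(thr))
      thr <- freezeThresholds(sc$stack, c("mCherry", "GFP"), 25, 1)
    f <- file.path(tmp, paste0("img", s, ".tif"))
    writeStack(sc$stack, f)
    paths <- c(paths, f)
    singles <- c(singles,
                 metrics(countMitolysosomes(sc$stack, thr))$n_mitolysosomes)
  }
  cfg <- runConfig("mitolysosomes", params = list(thresholds = as.list(thr)))
  man <- data.frame(image_id = paste0("img", 1:3), path = paths)
  out1 <- file.path(tmp, "res1.csv")
  out2 <- file.path(tmp, "res2.csv")
  tab <- batchRun(cfg, man, out1)
  expect_equal(tab$n_mitolysosomes, singles)
  expect_true(all(tab$status == "ok"))
  batchRun(cfg, man, out2)
  expect_identical(unname(tools::md5sum(out1)),
                   unname(tools::md5sum(out2)))

  # empty manifest: header-only table
  empty <- batchRun(cfg, data.frame(image_id = character(),
                                    path = character()))
  expect_equal(nrow(empty), 0L)

  # unreadable file is flagged without aborting the batch
  man_bad <- rbind(man, data.frame(image_id = "missing",
                                   path = file.path(tmp, "nope.tif")))
  tab2 <- batchRun(cfg, man_bad)
  expect_equal(sum(tab2$status == "ok"), 3L)
  expect_match(tab2$status[4], "error")
})
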