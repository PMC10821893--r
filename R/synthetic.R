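# Synthetic microscopy scenes and numeric cohorts with planted ground
# truth. The generators are pure functions of their parameter objects
# (including the seed): one pseudo-random stream per stack, split into
# substreams per object class, so turning noise on or off never moves
# object placement.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

.substreams <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Synthetic-scene parameters
#'
#' Parameter object consumed by \code{\link{generateReporterStack}} and
#' \code{\link{generateDnaStack}}. Defaults emulate the acquisition the
#' procedures were designed for: a 16 x 256 x 256 voxel confocal stack
#' at (0.5, 0.2, 0.2) um (a 0.5-um z-step), diffraction-limited puncta
#' rendered as isotropic Gaussian spots truncated at 3 sigma with
#' sigma = punctaRadius / 2, mitochondria as dilated 3D random-walk
#' tubes, and shot (Poisson) plus read-out (Gaussian) noise with a
#' Gaussian sd of 10 percent of the spot peak.
#'
#' @slot shape integer(3), voxels as (z, y, x).
#' @slot voxelSize numeric(3), um per voxel (dz, dy, dx).
#' @slot nMitoSegments number of mitochondrial tube segments.
#' @slot nMitolysosomes number of mCherry-only puncta to plant.
#' @slot punctaRadius punctum radius in px (spot sigma = radius / 2).
#' @slot nNuclei number of nuclei / cells (DNA scenes).
#' @slot nCytoDnaFoci number of DNA puncta planted outside organelles.
#' @slot nMitoNucleoids number of DNA puncta planted inside the
#'   mitochondrial network.
#' @slot backgroundAmplitude peak intensity of the additive per-slice
#'   linear background ramp (0 disables it).
#' @slot channelGains named intensity gains per channel role; the spot
#'   peak in a channel is its gain.
#' @slot noise list with \code{poissonScale} (photons per intensity
#'   unit; 0 disables shot noise) and \code{gaussianSd} (additive noise
#'   sd in intensity units).
#' @slot minSeparation minimum centre-to-centre distance between
#'   planted puncta, in px; must be at least 2 * punctaRadius so that
#'   planted puncta stay resolvable.
#' @slot fociCell if set, all cytosolic DNA foci are planted inside
#'   this cell ROI.
#' @slot seed integer RNG seed; identical parameters (including seed)
#'   give bit-identical scenes.
#' @aliases SceneParams
#' @exportClass SceneParams
setClass("SceneParams",
  representation(shape = "integer", voxelSize = "numeric",
                 nMitoSegments = "integer", nMitolysosomes = "integer",
                 punctaRadius = "numeric", nNuclei = "integer",
                 nCytoDnaFoci = "integer", nMitoNucleoids = "integer",
                 backgroundAmplitude = "numeric",
                 channelGains = "numeric", noise = "list",
                 minSeparation = "numeric", fociCell = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (any(object@shape <= 0L)) return("shape must be strictly positive")
    cnt <- c(object@nMitoSegments, object@nMitolysosomes,
             object@nNuclei, object@nCytoDnaFoci, object@nMitoNucleoids)
    if (any(cnt < 0L)) return("all counts must be >= 0")
    if (object@punctaRadius <= 0) return("punctaRadius must be > 0")
    if (object@minSeparation < 2 * object@punctaRadius)
      return("minSeparation must be >= 2 * punctaRadius")
    if (any(object@voxelSize <= 0)) return("voxelSize must be > 0")
    ns <- object@noise
    if (!all(c("poissonScale", "gaussianSd") %in% names(ns)))
      return("noise must list poissonScale and gaussianSd")
    if (ns$poissonScale < 0 || ns$gaussianSd < 0)
      return("noise parameters must be >= 0")
    TRUE
  })

#' @rdname SceneParams-class
#' @param shape,voxelSize,nMitoSegments,nMitolysosomes,punctaRadius
#'   see slots.
#' @param nNuclei,nCytoDnaFoci,nMitoNucleoids,backgroundAmplitude
#'   see slots.
#' @param channelGains,noise,minSeparation,fociCell,seed see slots;
#'   \code{minSeparation} defaults to 4 * punctaRadius.
#' @export
sceneParams <- function(shape = c(16L, 256L, 256L),
                        voxelSize = c(0.5, 0.2, 0.2),
                        nMitoSegments = 6L, nMitolysosomes = 30L,
                        punctaRadius = 3, nNuclei = 4L,
                        nCytoDnaFoci = 8L, nMitoNucleoids = 20L,
                        backgroundAmplitude = 0,
                        channelGains = c(mCherry = 100, GFP = 100,
                                         DNA = 100, TOMM20 = 100,
                                         DAPI = 100),
                        noise = list(poissonScale = 1, gaussianSd = 10),
                        minSeparation = NULL, fociCell = NA_integer_,
                        seed = 1L) {
  new("SceneParams", shape = as.integer(shape),
      voxelSize = as.numeric(voxelSize),
      nMitoSegments = as.integer(nMitoSegments),
      nMitolysosomes = as.integer(nMitolysosomes),
      punctaRadius = as.numeric(punctaRadius),
      nNuclei = as.integer(nNuclei),
      nCytoDnaFoci = as.integer(nCytoDnaFoci),
      nMitoNucleoids = as.integer(nMitoNucleoids),
      backgroundAmplitude = as.numeric(backgroundAmplitude),
      channelGains = channelGains, noise = noise,
      minSeparation = as.numeric(minSeparation %||% (4 * punctaRadius)),
      fociCell = as.integer(fociCell), seed = as.integer(seed))
}

#' Convenience: a noise-free copy of scene parameters
#' @param params a \linkS4class{SceneParams}
#' @return the same parameters with both noise terms set to 0
#' @export
noiseFree <- function(params) {
  params@noise <- list(poissonScale = 0, gaussianSd = 0)
  params
}

# ---- geometry helpers ------------------------------------------------

# random-walk tube skeletons; returns an n x 3 matrix of (y, x, z)
# voxel positions. Steps are shorter in z (anisotropic sections).
.tube_skeleton <- function(shape, nSegments, nSteps = 80L,
                           step = 1.5, avoid = NULL) {
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  pts <- matrix(numeric(0), 0L, 3L)
  zlo <- min(3, nz); zhi <- max(nz - 2, 1)
  for (s in seq_len(nSegments)) {
    for (try in 1:50) {
      pos <- c(runif(1, 8, ny - 8), runif(1, 8, nx - 8),
               runif(1, zlo, zhi))
      if (is.null(avoid) ||
          !avoid[round(pos[1]), round(pos[2]), round(pos[3])]) break
    }
    dir <- rnorm(3); dir[3] <- dir[3] * 0.3
    dir <- dir / sqrt(sum(dir^2))
    seg <- matrix(0, nSteps, 3L)
    k <- 0L
    for (i in seq_len(nSteps)) {
      cand <- pos + dir * step
      cand[1] <- min(max(cand[1], 4), ny - 3)
      cand[2] <- min(max(cand[2], 4), nx - 3)
      cand[3] <- min(max(cand[3], zlo), zhi)
      if (!is.null(avoid) &&
          avoid[round(cand[1]), round(cand[2]), round(cand[3])]) {
        dir <- rnorm(3); dir[3] <- dir[3] * 0.3
        dir <- dir / sqrt(sum(dir^2))
        next
      }
      pos <- cand
      k <- k + 1L
      seg[k, ] <- pos
      turn <- rnorm(3, sd = 0.35); turn[3] <- turn[3] * 0.3
      dir <- dir + turn
      dir <- dir / sqrt(sum(dir^2))
    }
    pts <- rbind(pts, seg[seq_len(k), , drop = FALSE])
  }
  pts
}

# dilate skeleton points into a tube mask [y, x, z]; in-plane radius
# rxy px, +/- rz slices in z
.stamp_tube <- function(shape, skel, rxy = 2, rz = 1) {
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  mask <- array(FALSE, c(ny, nx, nz))
  off <- expand.grid(dy = -ceiling(rxy):ceiling(rxy),
                     dx = -ceiling(rxy):ceiling(rxy), dz = -rz:rz)
  off <- off[(off$dy^2 + off$dx^2) / rxy^2 + off$dz^2 / (rz + 0.5)^2
             <= 1 + 1e-9, ]
  for (i in seq_len(nrow(skel))) {
    y <- round(skel[i, 1L]) + off$dy
    x <- round(skel[i, 2L]) + off$dx
    z <- round(skel[i, 3L]) + off$dz
    ok <- y >= 1 & y <= ny & x >= 1 & x <= nx & z >= 1 & z <= nz
    mask[cbind(y[ok], x[ok], z[ok])] <- TRUE
  }
  mask
}

# additive isotropic Gaussian spot, truncated at truncR voxels
.stamp_spot <- function(vol, center, sigma, truncR, amplitude,
                        clip = NULL) {
  d <- dim(vol)
  r <- ceiling(truncR)
  ys <- max(1, round(center[1]) - r):min(d[1], round(center[1]) + r)
  xs <- max(1, round(center[2]) - r):min(d[2], round(center[2]) + r)
  zs <- max(1, round(center[3]) - r):min(d[3], round(center[3]) + r)
  g <- expand.grid(y = ys, x = xs, z = zs)
  d2 <- (g$y - center[1])^2 + (g$x - center[2])^2 + (g$z - center[3])^2
  keep <- d2 <= truncR^2
  g <- g[keep, ]; d2 <- d2[keep]
  idx <- cbind(g$y, g$x, g$z)
  val <- amplitude * exp(-d2 / (2 * sigma^2))
  if (!is.null(clip)) {
    ok <- clip[idx]
    idx <- idx[ok, , drop = FALSE]; val <- val[ok]
  }
  vol[idx] <- vol[idx] + val
  vol
}

# rejection-sample n puncta centres (y, x, z) with pairwise separation
# >= minSep, margins, and optional keep-out voxel set / allowed 2D region
.place_puncta <- function(shape, n, minSep, margin_xy, margin_z,
                          keepout = NULL, keepout_dist = 0,
                          allowed2d = NULL, edge2d = NULL,
                          edge2d_dist = 0, maxTries = NULL) {
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  if (ny - 2 * margin_xy < 1 || nx - 2 * margin_xy < 1 ||
      nz - 2 * margin_z < 1)
    stop("scene too small for the requested puncta margins")
  maxTries <- maxTries %||% (200L * n)
  centers <- matrix(numeric(0), 0L, 3L)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("placement failure: could not honour min_separation = ",
           minSep, " after ", maxTries, " tries (over-dense scene)")
    cand <- c(runif(1, 1 + margin_xy, ny - margin_xy),
              runif(1, 1 + margin_xy, nx - margin_xy),
              runif(1, 1 + margin_z, nz - margin_z))
    if (!is.null(allowed2d) &&
        !allowed2d[round(cand[1]), round(cand[2])]) next
    if (nrow(centers) &&
        min(sqrt(colSums((t(centers) - cand)^2))) < minSep) next
    if (!is.null(keepout) && nrow(keepout) &&
        min(sqrt(colSums((t(keepout) - cand)^2))) < keepout_dist) next
    if (!is.null(edge2d) && nrow(edge2d) &&
        min((edge2d[, 1L] - cand[1L])^2 +
            (edge2d[, 2L] - cand[2L])^2) < edge2d_dist^2) next
    centers <- rbind(centers, cand)
  }
  centers
}

.apply_noise <- function(vol, noise) {
  if (noise$poissonScale > 0)
    vol[] <- rpois(length(vol), pmax(vol, 0) * noise$poissonScale) /
      noise$poissonScale
  if (noise$gaussianSd > 0)
    vol[] <- vol + rnorm(length(vol), 0, noise$gaussianSd)
  pmax(vol, 0)
}

.background_ramp <- function(shape, amplitude) {
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  if (amplitude == 0) return(array(0, c(ny, nx, nz)))
  ramp <- matrix(rep(seq(0, 1, length.out = nx), each = ny), ny, nx)
  array(rep(amplitude * ramp, nz), c(ny, nx, nz))
}

# intensity of the mitochondrial network relative to the spot peak
.TUBE_LEVEL <- 1.2
.NUCLEOID_LEVEL <- 0.6
.NUCLEUS_LEVEL <- 0.9

# ---- generators ------------------------------------------------------

#' Generate a synthetic mito-QC reporter stack
#'
#' Renders a two-channel (mCherry, GFP) z-stack in which the
#' mitochondrial network (dilated 3D random-walk tubes) is present in
#' both channels and mitolysosomes are Gaussian-profile puncta present
#' in mCherry only, mimicking lysosomal quenching of GFP. An optional
#' per-slice linear background ramp and Poisson-then-Gaussian noise are
#' applied per channel. Every planted object is registered in the
#' returned \linkS4class{SceneTruth}.
#'
#' @param params a \linkS4class{SceneParams}.
#' @return list with \code{stack} (an \linkS4class{ImageStack} with
#'   channels mCherry, GFP) and \code{truth} (a
#'   \linkS4class{SceneTruth}).
#' @examples
#' sc <- generateReporterStack(sceneParams(shape = c(8L, 96L, 96L),
#'                                         nMitolysosomes = 5L,
#'                                         seed = 7L))
#' sc$stack
#' nrow(truthObjects(sc$truth, "mitolysosome"))
#' @export
generateReporterStack <- function(params) {
  validObject(params)
  sh <- params@shape
  ny <- sh[2L]; nx <- sh[3L]; nz <- sh[1L]
  seeds <- .substreams(params@seed, 3L)
  sigma <- params@punctaRadius / 2
  trunc <- 3 * sigma

  tube <- .with_seed(seeds[1L], {
    skel <- .tube_skeleton(sh, params@nMitoSegments)
    .stamp_tube(sh, skel)
  })
  tube_vox <- which(tube, arr.ind = TRUE)  # (y, x, z)
  tube_vox <- tube_vox[, c(1L, 2L, 3L), drop = FALSE]

  centers <- .with_seed(seeds[2L], .place_puncta(
    sh, params@nMitolysosomes, params@minSeparation,
    margin_xy = ceiling(trunc) + 2, margin_z = min(ceiling(trunc) + 1,
                                                   floor((nz - 1) / 2)),
    keepout = tube_vox, keepout_dist = trunc + 3))

  mito <- array(0, c(ny, nx, nz))
  mito[tube] <- .TUBE_LEVEL
  spots <- array(0, c(ny, nx, nz))
  for (i in seq_len(nrow(centers)))
    spots <- .stamp_spot(spots, centers[i, ], sigma, trunc, 1.0)

  bg <- .background_ramp(sh, params@backgroundAmplitude)
  gains <- params@channelGains
  mcherry <- gains[["mCherry"]] * (mito + spots) + bg
  gfp <- gains[["GFP"]] * mito + bg

  chans <- .with_seed(seeds[3L], list(
    mCherry = .apply_noise(mcherry, params@noise),
    GFP = .apply_noise(gfp, params@noise)))

  obj <- data.frame(kind = character(), z = numeric(), y = numeric(),
                    x = numeric(), extent = numeric())
  if (nrow(centers))
    obj <- rbind(obj, data.frame(
      kind = "mitolysosome", z = centers[, 3L], y = centers[, 1L],
      x = centers[, 2L], extent = params@punctaRadius))
  if (nrow(tube_vox))
    obj <- rbind(obj, data.frame(
      kind = "mitochondrion_segment",
      z = mean(tube_vox[, 3L]), y = mean(tube_vox[, 1L]),
      x = mean(tube_vox[, 2L]), extent = sum(tube)))
  truth <- new("SceneTruth", objects = obj,
               cellRois = matrix(1L, ny, nx))
  list(stack = ImageStack(chans, voxelSize = params@voxelSize),
       truth = truth)
}

#' Generate a synthetic DNA / TOMM20 / DAPI stack
#'
#' Renders the input of the cytosolic DNA-focus assay: DAPI shows
#' ellipsoidal nuclei, TOMM20 a mitochondrial tube network avoiding the
#' nuclei, and the anti-DNA channel the sum of nuclear signal,
#' mitochondrial nucleoids confined to the network, and
#' \code{nCytoDnaFoci} puncta planted strictly outside both organelle
#' footprints. Cell ROIs are the Voronoi tiles of the nucleus centres
#' and label every planted focus.
#'
#' @inheritParams generateReporterStack
#' @return list with \code{stack} (channels DNA, TOMM20, DAPI),
#'   \code{truth} (cytosolic foci carry a \code{cell} column), and the
#'   ROI label image in \code{truth}.
#' @export
generateDnaStack <- function(params) {
  validObject(params)
  if (params@nNuclei < 1L) stop("generateDnaStack needs nNuclei >= 1")
  sh <- params@shape
  ny <- sh[2L]; nx <- sh[3L]; nz <- sh[1L]
  seeds <- .substreams(params@seed, 4L)
  sigma <- params@punctaRadius / 2
  trunc <- 3 * sigma

  # nuclei and cell ROIs
  geom <- .with_seed(seeds[1L], {
    ncent <- .place_puncta(
      sh, params@nNuclei,
      minSep = 0.6 * min(ny, nx) / max(1, sqrt(params@nNuclei)),
      margin_xy = ceiling(0.12 * min(ny, nx)), margin_z = 0,
      maxTries = 20000L)
    ncent[, 3L] <- nz / 2 + runif(params@nNuclei, -1, 1)
    ncent
  })
  rz <- max(2, round(nz / 4)); rxy <- round(0.07 * min(ny, nx))
  nuc <- array(FALSE, c(ny, nx, nz))
  gy <- slice.index(nuc, 1L); gx <- slice.index(nuc, 2L)
  gz <- slice.index(nuc, 3L)
  for (i in seq_len(nrow(geom)))
    nuc <- nuc | ((gy - geom[i, 1L])^2 / rxy^2 +
                  (gx - geom[i, 2L])^2 / rxy^2 +
                  (gz - geom[i, 3L])^2 / rz^2 <= 1)
  # Voronoi cell ROIs over (y, x): tiles the field
  py <- matrix(rep(seq_len(ny), nx), ny, nx)
  px <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  dist2 <- vapply(seq_len(nrow(geom)), function(i)
    (py - geom[i, 1L])^2 + (px - geom[i, 2L])^2,
    matrix(0, ny, nx))
  rois <- matrix(max.col(matrix(-dist2, ny * nx, nrow(geom)),
                         ties.method = "first"), ny, nx)

  # keep-out region: nuclei enlarged by a safety margin
  nuc_avoid <- array(FALSE, c(ny, nx, nz))
  for (i in seq_len(nrow(geom)))
    nuc_avoid <- nuc_avoid | ((gy - geom[i, 1L])^2 / (rxy + 4)^2 +
                              (gx - geom[i, 2L])^2 / (rxy + 4)^2 +
                              (gz - geom[i, 3L])^2 / (rz + 2)^2 <= 1)
  tube <- .with_seed(seeds[2L], {
    skel <- .tube_skeleton(sh, params@nMitoSegments, avoid = nuc_avoid)
    .stamp_tube(sh, skel)
  })
  tube <- tube & !nuc_avoid
  tube_vox <- which(tube, arr.ind = TRUE)

  placed <- .with_seed(seeds[3L], {
    # nucleoids sit on interior network voxels (all in-plane neighbours
    # also in the network), so their truncated spots stay confined
    int_ok <- rep(TRUE, nrow(tube_vox))
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- tube_vox[, 1L] + dy
      xx <- tube_vox[, 2L] + dx
      inb <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
      nb <- rep(FALSE, nrow(tube_vox))
      nb[inb] <- tube[cbind(yy[inb], xx[inb], tube_vox[inb, 3L])]
      int_ok <- int_ok & nb
    }
    int_vox <- tube_vox[int_ok, , drop = FALSE]
    nnuc <- min(params@nMitoNucleoids, nrow(int_vox))
    nucleoids <- if (nnuc > 0L)
      int_vox[sample.int(nrow(int_vox), nnuc), , drop = FALSE]
    else matrix(numeric(0), 0L, 3L)
    nuc_vox <- which(nuc, arr.ind = TRUE)
    keepout <- rbind(tube_vox, nuc_vox)
    allowed <- if (is.na(params@fociCell)) NULL else
      (rois == params@fociCell)
    # manually drawn cell outlines would never cut through a focus, so
    # planted foci keep clear of ROI boundaries
    edge <- which(rois != rois[c(2:ny, ny), ] |
                  rois != rois[, c(2:nx, nx)], arr.ind = TRUE)
    foci <- .place_puncta(
      sh, params@nCytoDnaFoci, params@minSeparation,
      margin_xy = ceiling(trunc) + 2,
      margin_z = min(ceiling(trunc) + 1, floor((nz - 1) / 2)),
      keepout = keepout, keepout_dist = trunc + 4, allowed2d = allowed,
      edge2d = edge, edge2d_dist = trunc + 2)
    list(nucleoids = nucleoids, foci = foci)
  })

  dna <- array(0, c(ny, nx, nz))
  dna[nuc] <- .NUCLEUS_LEVEL
  for (i in seq_len(nrow(placed$nucleoids)))
    dna <- .stamp_spot(dna, placed$nucleoids[i, ], sigma = 1,
                       truncR = 2, amplitude = .NUCLEOID_LEVEL,
                       clip = tube)
  for (i in seq_len(nrow(placed$foci)))
    dna <- .stamp_spot(dna, placed$foci[i, ], sigma, trunc, 1.0)

  tub_img <- array(0, c(ny, nx, nz)); tub_img[tube] <- .TUBE_LEVEL
  dap_img <- array(0, c(ny, nx, nz)); dap_img[nuc] <- 1.0

  bg <- .background_ramp(sh, params@backgroundAmplitude)
  gains <- params@channelGains
  chans <- .with_seed(seeds[4L], list(
    DNA = .apply_noise(gains[["DNA"]] * dna + bg, params@noise),
    TOMM20 = .apply_noise(gains[["TOMM20"]] * tub_img + bg,
                          params@noise),
    DAPI = .apply_noise(gains[["DAPI"]] * dap_img + bg, params@noise)))

  obj <- data.frame(kind = character(), z = numeric(), y = numeric(),
                    x = numeric(), extent = numeric(), cell = integer())
  if (nrow(geom))
    obj <- rbind(obj, data.frame(
      kind = "nucleus", z = geom[, 3L], y = geom[, 1L], x = geom[, 2L],
      extent = rxy, cell = seq_len(nrow(geom))))
  if (nrow(placed$nucleoids))
    obj <- rbind(obj, data.frame(
      kind = "mito_nucleoid", z = placed$nucleoids[, 3L],
      y = placed$nucleoids[, 1L], x = placed$nucleoids[, 2L],
      extent = 2, cell = rois[placed$nucleoids[, 1:2, drop = FALSE]]))
  if (nrow(placed$foci))
    obj <- rbind(obj, data.frame(
      kind = "cyto_dna_focus", z = placed$foci[, 3L],
      y = placed$foci[, 1L], x = placed$foci[, 2L],
      extent = params@punctaRadius,
      cell = rois[round(placed$foci[, 1:2, drop = FALSE])]))
  truth <- new("SceneTruth", objects = obj, cellRois = rois)
  list(stack = ImageStack(chans, voxelSize = params@voxelSize),
       truth = truth)
}

#' qPCR cohort parameters
#'
#' @param nPerGroup samples per group (young, old).
#' @param foldChange expected old/young ratio of the
#'   cytosolic/mitochondrial mtDNA ratio (> 0); young samples have an
#'   expected cytosolic/mitochondrial ratio of 1.
#' @param ctNoiseSd Gaussian noise sd added to every Ct, in cycles.
#' @param baselineCts named baseline Ct per gene (mitochondrial
#'   fraction) and for nuclear 18S.
#' @param genes mtDNA-encoded genes to simulate.
#' @param seed RNG seed.
#' @return a validated list of class \code{CohortParams}.
#' @export
cohortParams <- function(nPerGroup = 8L, foldChange = 10,
                         ctNoiseSd = 0.3,
                         baselineCts = c(`18S` = 12, `mt-Nd2` = 18,
                                         `mt-Co1` = 17.5,
                                         `mt-Cytb` = 18.5),
                         genes = c("mt-Nd2", "mt-Co1", "mt-Cytb"),
                         seed = 1L) {
  stopifnot(foldChange > 0, ctNoiseSd >= 0, nPerGroup >= 0)
  if (!all(c(genes, "18S") %in% names(baselineCts)))
    stop("baselineCts must cover every gene and 18S")
  structure(list(nPerGroup = as.integer(nPerGroup),
                 foldChange = foldChange, ctNoiseSd = ctNoiseSd,
                 baselineCts = baselineCts, genes = genes,
                 seed = as.integer(seed)),
            class = "CohortParams")
}

#' Generate a fraction-resolved qPCR cohort
#'
#' Draws Ct values for young and old samples across cytosolic and
#' mitochondrial fractions (plus nuclear 18S per sample) such that the
#' noise-free cytosolic/mitochondrial abundance ratio
#' \eqn{2^{-(Ct_{cyto} - Ct_{mito})}} equals 1 for young samples and
#' \code{foldChange} for old samples, for every gene. Gaussian Ct noise
#' of sd \code{ctNoiseSd} is added independently to every measurement.
#'
#' @param params a \code{\link{cohortParams}} object.
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{fraction}, \code{gene}, \code{ct}.
#' @export
generateQpcrCohort <- function(params) {
  stopifnot(inherits(params, "CohortParams"))
  if (params$nPerGroup == 0L)
    return(data.frame(sample_id = character(), group = character(),
                      fraction = character(), gene = character(),
                      ct = numeric()))
  .with_seed(params$seed, {
    rows <- list()
    for (grp in c("young", "old")) {
      ratio <- if (grp == "young") 1 else params$foldChange
      for (i in seq_len(params$nPerGroup)) {
        sid <- paste0(grp, "_", i)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = grp, fraction = "nuclear",
          gene = "18S",
          ct = params$baselineCts[["18S"]] + rnorm(1, 0, params$ctNoiseSd))
        for (g in params$genes) {
          base <- params$baselineCts[[g]]
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = grp, fraction = "mitochondrial",
            gene = g, ct = base + rnorm(1, 0, params$ctNoiseSd))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = grp, fraction = "cytosolic",
            gene = g,
            ct = base - log2(ratio) + rnorm(1, 0, params$ctNoiseSd))
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a two-group measurement cohort
#'
#' Produces a labelled two-group table with a configurable location
#' shift, for exercising the normality-gated test policy. The shift is
#' \code{effectSize} standard deviations of the base distribution;
#' \code{distribution = "lognormal"} (meanlog 0, sdlog 1) yields data
#' that fails normality screening at moderate n.
#'
#' @param nPerGroup units per group (>= 2).
#' @param effectSize location shift in base-distribution sd units.
#' @param distribution "normal" or "lognormal".
#' @param seed RNG seed.
#' @return data.frame with columns \code{unit_id}, \code{group},
#'   \code{value}.
#' @export
generateMeasurementCohort <- function(nPerGroup, effectSize = 0,
                                      distribution = c("normal",
                                                       "lognormal"),
                                      seed = 1L) {
  stopifnot(nPerGroup >= 2)
  distribution <- match.arg(distribution)
  .with_seed(seed, {
    draw <- switch(distribution,
      normal = function(n) rnorm(n),
      lognormal = function(n) rlnorm(n))
    sd0 <- switch(distribution, normal = 1,
                  lognormal = sqrt((exp(1) - 1) * exp(1)))
    v1 <- draw(nPerGroup)
    v2 <- draw(nPerGroup) + effectSize * sd0
    data.frame(
      unit_id = c(paste0("g1_", seq_len(nPerGroup)),
                  paste0("g2_", seq_len(nPerGroup))),
      group = rep(c("g1", "g2"), each = nPerGroup),
      value = c(v1, v2))
  })
}
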