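# The named quantification procedures, composed from the primitive
# operators. Each procedure echoes every parameter needed to re-run it
# and expects batch-frozen thresholds: one numeric threshold per
# channel, computed once (e.g. by Otsu on a designated reference image)
# and reused verbatim for every image of a batch.

.need_channels <- function(stack, channels) {
  miss <- setdiff(channels, channelNames(stack))
  if (length(miss))
    stop("missing channel(s): ", paste(miss, collapse = ", "))
}

.need_thresholds <- function(thresholds, channels) {
  if (is.null(thresholds) || !all(channels %in% names(thresholds)))
    stop("unset batch threshold for channel(s): ",
         paste(setdiff(channels, names(thresholds)), collapse = ", "),
         "; freeze thresholds for the batch first ",
         "(see freezeThresholds)")
}

.preprocess <- function(stack, channel, radius, sigma = NULL,
                        despeckle = FALSE) {
  v <- getChannel(stack, channel)
  if (despeckle) v <- medianDespeckle(v)
  v <- rollingBallSubtract(v, radius)
  if (!is.null(sigma)) v <- gaussianBlur(v, sigma)
  v
}

#' Freeze batch thresholds on a reference image
#'
#' Applies a procedure's preprocessing (rolling-ball subtraction plus
#' optional Gaussian blur) to the given channels of a reference stack
#' and computes one Otsu threshold per channel. The returned named
#' vector is then passed unchanged to every image of the batch,
#' mirroring the convention that the same threshold is applied to each
#' image of an experiment.
#'
#' @param reference an \linkS4class{ImageStack}.
#' @param channels channel role names to threshold.
#' @param radius rolling-ball radius in px.
#' @param sigma Gaussian blur sigma in px (NULL to skip the blur).
#' @param despeckle apply the 3x3 median despeckle first.
#' @return named numeric vector of thresholds.
#' @export
freezeThresholds <- function(reference, channels, radius = 25,
                             sigma = 1, despeckle = FALSE) {
  .need_channels(reference, channels)
  vapply(channels, function(ch)
    otsuThreshold(.preprocess(reference, ch, radius, sigma, despeckle)),
    numeric(1))
}

#' Count mitolysosomes in a two-channel reporter stack
#'
#' The mito-QC readout: both reporter channels are background-
#' subtracted (rolling ball, default radius 25 px) and blurred
#' (default sigma 1 px); each is thresholded with its batch-frozen
#' value; the GFP-positive mask is subtracted from the mCherry-positive
#' mask; surviving mCherry-only signal is counted as 3D connected
#' components. The calibrated volume of the GFP-positive mask is
#' reported as mitochondrial mass.
#'
#' @param stack \linkS4class{ImageStack} with channels mCherry and GFP.
#' @param thresholds named numeric, batch-frozen thresholds for
#'   \code{mCherry} and \code{GFP} (see \code{\link{freezeThresholds}}).
#' @param radius rolling-ball radius in px.
#' @param sigma Gaussian blur sigma in px.
#' @param connectivity 3D connectivity for object counting (6 or 26).
#' @param minVoxels,maxVoxels object size filter in voxels. The
#'   counting procedures default to \code{minVoxels = 8}: a
#'   diffraction-limited punctum thresholded near half peak spans well
#'   over 10 voxels at this calibration, while threshold-flicker
#'   fragments along mask edges under shot noise stay below ~6, so the
#'   floor rejects noise fragments without touching real puncta.
#' @param imageId identifier echoed in the result.
#' @return a \linkS4class{QuantResult} with metrics
#'   \code{n_mitolysosomes}, \code{mitochondrial_mass_um3} and
#'   \code{mitolysosome_volume_um3}; the object table is in
#'   \code{resultDetails(x)$objects}.
#' @export
countMitolysosomes <- function(stack, thresholds, radius = 25,
                               sigma = 1, connectivity = 26L,
                               minVoxels = 8L, maxVoxels = Inf,
                               imageId = "image") {
  .need_channels(stack, c("mCherry", "GFP"))
  .need_thresholds(thresholds, c("mCherry", "GFP"))
  mch <- .preprocess(stack, "mCherry", radius, sigma)
  gfp <- .preprocess(stack, "GFP", radius, sigma)
  vs <- voxelSize(stack)
  m_mch <- BinaryMask(mch > thresholds[["mCherry"]], vs,
                      list(channel = "mCherry",
                           threshold = thresholds[["mCherry"]]))
  m_gfp <- BinaryMask(gfp > thresholds[["GFP"]], vs,
                      list(channel = "GFP",
                           threshold = thresholds[["GFP"]]))
  mlyso <- maskSubtract(m_mch, m_gfp)
  lab <- labelObjects3D(mlyso, connectivity, minVoxels, maxVoxels,
                        intensity = mch)
  QuantResult(
    imageId, "count_mitolysosomes",
    metrics = list(
      n_mitolysosomes = nrow(lab$objects),
      mitochondrial_mass_um3 = sum(maskData(m_gfp)) * prod(vs),
      mitolysosome_volume_um3 = sum(lab$objects$volume_um3)),
    params = list(radius = radius, sigma = sigma,
                  thresholds = as.list(thresholds),
                  connectivity = connectivity, minVoxels = minVoxels,
                  maxVoxels = maxVoxels),
    details = list(objects = lab$objects))
}

#' Count autophagy structures (single- and double-positive puncta)
#'
#' Same preprocessing and thresholding as
#' \code{\link{countMitolysosomes}}; reports 3D object counts for each
#' requested channel mask and for the intersection of each requested
#' channel pair (e.g. LC3+LAMP1+ autolysosomes, LC3+GFP+
#' mitophagosomes).
#'
#' @inheritParams countMitolysosomes
#' @param channels channel role names to count individually.
#' @param pairs list of length-2 character vectors to count as
#'   double-positive structures.
#' @return a \linkS4class{QuantResult} with metrics \code{n_<channel>}
#'   and \code{n_<a>_<b>}.
#' @export
countAutophagyStructures <- function(stack, thresholds,
                                     channels = c("LC3", "LAMP1"),
                                     pairs = list(c("LC3", "LAMP1")),
                                     radius = 25, sigma = 1,
                                     connectivity = 26L, minVoxels = 8L,
                                     maxVoxels = Inf,
                                     imageId = "image") {
  all_ch <- union(channels, unlist(pairs))
  .need_channels(stack, all_ch)
  .need_thresholds(thresholds, all_ch)
  vs <- voxelSize(stack)
  masks <- lapply(all_ch, function(ch)
    BinaryMask(.preprocess(stack, ch, radius, sigma) >
                 thresholds[[ch]], vs,
               list(channel = ch, threshold = thresholds[[ch]])))
  names(masks) <- all_ch
  count1 <- function(m)
    nrow(labelObjects3D(m, connectivity, minVoxels, maxVoxels)$objects)
  metrics <- list()
  for (ch in channels)
    metrics[[paste0("n_", ch)]] <- count1(masks[[ch]])
  for (p in pairs)
    metrics[[paste0("n_", p[1L], "_", p[2L])]] <-
      count1(maskIntersect(masks[[p[1L]]], masks[[p[2L]]]))
  QuantResult(imageId, "count_autophagy_structures", metrics,
              params = list(radius = radius, sigma = sigma,
                            thresholds = as.list(thresholds),
                            connectivity = connectivity,
                            minVoxels = minVoxels,
                            maxVoxels = maxVoxels))
}

#' Phospho-ubiquitin (Ser65) levels
#'
#' Despeckle, rolling-ball background subtraction (default radius 25),
#' maximal projection; then either the mean fluorescence intensity per
#' cell ROI (\code{mode = "cell_mfi"}) or the thresholded positive area
#' fraction of the projection (\code{mode = "tissue_area"}).
#'
#' @inheritParams countMitolysosomes
#' @param mode \code{"cell_mfi"} or \code{"tissue_area"}.
#' @param cellRois integer label matrix \code{[y, x]}; required in
#'   cell mode.
#' @param threshold intensity threshold for tissue-area mode.
#' @param channel channel role carrying the pUb signal.
#' @return a \linkS4class{QuantResult}; cell mode fills the per-cell
#'   table and reports their mean as \code{mfi}.
#' @export
quantifyPUb <- function(stack, mode = c("cell_mfi", "tissue_area"),
                        cellRois = NULL, threshold = NULL, radius = 25,
                        channel = "pUb", imageId = "image") {
  mode <- match.arg(mode)
  .need_channels(stack, channel)
  proj <- maxProject(.preprocess(stack, channel, radius, sigma = NULL,
                                 despeckle = TRUE))
  params <- list(radius = radius, mode = mode, channel = channel,
                 threshold = threshold)
  if (mode == "cell_mfi") {
    if (is.null(cellRois)) stop("cell_mfi mode requires cellRois")
    cells <- sort(unique(as.vector(cellRois)))
    cells <- cells[cells > 0]
    per <- data.frame(
      cell = cells,
      mfi = vapply(cells, function(k)
        mean(proj[cellRois == k]), numeric(1)))
    QuantResult(imageId, "quantify_pub",
                metrics = list(mfi = mean(per$mfi)),
                params = params, perCell = per)
  } else {
    if (is.null(threshold))
      stop("tissue_area mode requires a batch-frozen threshold")
    QuantResult(imageId, "quantify_pub",
                metrics = list(area_fraction =
                                 areaFraction(proj > threshold)),
                params = params)
  }
}

#' Count cytosolic DNA foci per cell
#'
#' All three channels are background-subtracted (rolling ball, default
#' radius 25 px) and blurred (default sigma 0.75 px). TOMM20 and DAPI
#' are thresholded with batch-frozen values; their union is the
#' organelle exclusion mask. The DNA signal is zeroed inside the
#' exclusion mask (signal-level subtraction), maximum-projected, and
#' prominence-based maxima are counted within each cell ROI. The maxima
#' tolerance is a fraction of the field-level dynamic range of the
#' residual projection, shared by all ROIs of the field.
#'
#' @inheritParams countMitolysosomes
#' @param cellRois integer label matrix \code{[y, x]} delineating
#'   cells; ROIs must tile the field (every planted focus belongs to
#'   one).
#' @param thresholds named numeric, batch-frozen thresholds for
#'   \code{TOMM20} and \code{DAPI}.
#' @param sigma Gaussian blur sigma in px (default 0.75).
#' @param tolerance absolute maxima (noise) tolerance on the intensity
#'   scale. The default, the larger of the two frozen organelle
#'   thresholds, exploits a structural bound: zeroing inside the
#'   exclusion mask leaves residual halos around organelles whose
#'   intensity cannot exceed the threshold that cut the mask (any
#'   brighter voxel would have been excluded), so a tolerance at that
#'   level silences every halo while genuine foci, which must stand
#'   clear of organelle-level signal to be called cytosolic, remain
#'   above it.
#' @return a \linkS4class{QuantResult} with metric \code{n_foci_total},
#'   per-cell counts in \code{perCell}, and maxima coordinates in
#'   \code{resultDetails(x)$maxima}.
#' @export
countCytosolicDnaFoci <- function(stack, cellRois, thresholds,
                                  radius = 25, sigma = 0.75,
                                  tolerance = NULL,
                                  imageId = "image") {
  .need_channels(stack, c("DNA", "TOMM20", "DAPI"))
  .need_thresholds(thresholds, c("TOMM20", "DAPI"))
  if (is.null(cellRois) || !any(cellRois > 0)) stop("empty ROI set")
  dna <- .preprocess(stack, "DNA", radius, sigma)
  tom <- .preprocess(stack, "TOMM20", radius, sigma)
  dap <- .preprocess(stack, "DAPI", radius, sigma)
  vs <- voxelSize(stack)
  excl <- maskUnion(
    BinaryMask(tom > thresholds[["TOMM20"]], vs),
    BinaryMask(dap > thresholds[["DAPI"]], vs))
  residual <- dna
  residual[maskData(excl)] <- 0
  proj <- maxProject(residual)
  tol <- tolerance %||% max(thresholds[["TOMM20"]],
                            thresholds[["DAPI"]])
  cells <- sort(unique(as.vector(cellRois)))
  cells <- cells[cells > 0]
  pts_all <- list()
  per <- data.frame(cell = cells, n_foci = NA_integer_)
  for (i in seq_along(cells)) {
    reg <- cellRois == cells[i]
    pts <- findMaxima(proj, tol, region = reg)
    per$n_foci[i] <- nrow(pts)
    if (nrow(pts)) pts$cell <- cells[i]
    pts_all[[i]] <- pts
  }
  maxima <- do.call(rbind, pts_all[vapply(pts_all, nrow, 0L) > 0])
  if (is.null(maxima))
    maxima <- data.frame(y = numeric(), x = numeric(),
                         value = numeric(), cell = integer())
  QuantResult(
    imageId, "count_cytosolic_dna_foci",
    metrics = list(n_foci_total = sum(per$n_foci)),
    params = list(radius = radius, sigma = sigma,
                  thresholds = as.list(thresholds), tolerance = tol),
    perCell = per, details = list(maxima = maxima))
}

#' Count 4-HNE aggregates
#'
#' Rolling-ball background subtraction (default radius 15 px), Gaussian
#' blur (default sigma 0.75 px), batch-frozen threshold, 3D object
#' counting.
#'
#' @inheritParams countMitolysosomes
#' @param channel channel role carrying the 4-HNE signal.
#' @param sigma Gaussian blur sigma in px.
#' @return a \linkS4class{QuantResult} with metrics
#'   \code{n_aggregates} and \code{aggregate_volume_um3}.
#' @export
countHneAggregates <- function(stack, thresholds, radius = 15,
                               sigma = 0.75, channel = "HNE",
                               connectivity = 26L, minVoxels = 8L,
                               maxVoxels = Inf, imageId = "image") {
  .need_channels(stack, channel)
  .need_thresholds(thresholds, channel)
  v <- .preprocess(stack, channel, radius, sigma)
  m <- BinaryMask(v > thresholds[[channel]], voxelSize(stack),
                  list(channel = channel,
                       threshold = thresholds[[channel]]))
  lab <- labelObjects3D(m, connectivity, minVoxels, maxVoxels,
                        intensity = v)
  QuantResult(
    imageId, "count_hne_aggregates",
    metrics = list(n_aggregates = nrow(lab$objects),
                   aggregate_volume_um3 = sum(lab$objects$volume_um3)),
    params = list(radius = radius, sigma = sigma, channel = channel,
                  thresholds = as.list(thresholds),
                  connectivity = connectivity, minVoxels = minVoxels,
                  maxVoxels = maxVoxels),
    details = list(objects = lab$objects))
}

#' cGAS-DNA colocalization
#'
#' Both channels are background-subtracted (rolling ball, default
#' radius 20 px) and blurred (default sigma 0.75 px), thresholded with
#' batch-frozen values, and the Manders overlap coefficient of the
#' preprocessed intensities is computed over the union of the two
#' masks.
#'
#' @inheritParams countMitolysosomes
#' @param sigma Gaussian blur sigma in px.
#' @return a \linkS4class{QuantResult} with metric
#'   \code{overlap_coefficient}.
#' @export
cgasDnaOverlap <- function(stack, thresholds, radius = 20,
                           sigma = 0.75, imageId = "image") {
  .need_channels(stack, c("cGAS", "DNA"))
  .need_thresholds(thresholds, c("cGAS", "DNA"))
  cg <- .preprocess(stack, "cGAS", radius, sigma)
  dn <- .preprocess(stack, "DNA", radius, sigma)
  r <- overlapCoefficient(cg, dn,
                          maskA = cg > thresholds[["cGAS"]],
                          maskB = dn > thresholds[["DNA"]])
  QuantResult(imageId, "cgas_dna_overlap",
              metrics = list(overlap_coefficient = r),
              params = list(radius = radius, sigma = sigma,
                            thresholds = as.list(thresholds)))
}

#' Cardiolipin (NAO) quantification and NAO-TOMM20 colocalization
#'
#' Mean fluorescence intensity of the NAO channel in the maximal
#' projection, plus the Manders overlap coefficient between the NAO and
#' TOMM20 volumes (cardiolipin translocation readout).
#'
#' @inheritParams countMitolysosomes
#' @return a \linkS4class{QuantResult} with metrics \code{nao_mfi} and
#'   \code{overlap_coefficient}.
#' @export
cardiolipinQuant <- function(stack, imageId = "image") {
  .need_channels(stack, c("NAO", "TOMM20"))
  nao <- getChannel(stack, "NAO")
  tom <- getChannel(stack, "TOMM20")
  QuantResult(imageId, "cardiolipin_quant",
              metrics = list(
                nao_mfi = mean(maxProject(nao)),
                overlap_coefficient = overlapCoefficient(nao, tom)),
              params = list())
}

#' Marker mean fluorescence intensity in the maximal projection
#'
#' @inheritParams countMitolysosomes
#' @param channel channel role to quantify (e.g. p62, ubiquitin).
#' @return a \linkS4class{QuantResult} with metric \code{mfi}.
#' @export
markerMfi <- function(stack, channel, imageId = "image") {
  .need_channels(stack, channel)
  QuantResult(imageId, "marker_mfi",
              metrics = list(mfi = mean(maxProject(stack, channel))),
              params = list(channel = channel))
}

# registry used by the batch runner
.PROCEDURES <- list(
  mitolysosomes = function(stack, rois, p, id)
    countMitolysosomes(stack, thresholds = p$thresholds,
                       radius = p$radius %||% 25,
                       sigma = p$sigma %||% 1,
                       connectivity = p$connectivity %||% 26L,
                       minVoxels = p$minVoxels %||% 8L,
                       maxVoxels = p$maxVoxels %||% Inf, imageId = id),
  cyto_dna_foci = function(stack, rois, p, id)
    countCytosolicDnaFoci(stack, cellRois = rois,
                          thresholds = p$thresholds,
                          radius = p$radius %||% 25,
                          sigma = p$sigma %||% 0.75,
                          tolerance = p$tolerance,
                          imageId = id),
  hne_aggregates = function(stack, rois, p, id)
    countHneAggregates(stack, thresholds = p$thresholds,
                       radius = p$radius %||% 15,
                       sigma = p$sigma %||% 0.75,
                       channel = p$channel %||% "HNE", imageId = id),
  cgas_dna_overlap = function(stack, rois, p, id)
    cgasDnaOverlap(stack, thresholds = p$thresholds,
                   radius = p$radius %||% 20,
                   sigma = p$sigma %||% 0.75, imageId = id),
  cardiolipin = function(stack, rois, p, id)
    cardiolipinQuant(stack, imageId = id),
  marker_mfi = function(stack, rois, p, id)
    markerMfi(stack, channel = p$channel, imageId = id))

#' Batch-run a quantification procedure over an image manifest
#'
#' Runs one procedure (with batch-frozen parameters from the config)
#' over every image of a manifest, one result row per image. Per-image
#' failures are caught, logged in the \code{status} column and do not
#' abort the batch. Output is deterministic given the config and
#' manifest; written CSVs are byte-identical across reruns.
#'
#' @param config a \code{\link{runConfig}}.
#' @param manifest data.frame with columns \code{image_id},
#'   \code{path} and optionally \code{roi_path} (TIFF label image), or
#'   a named list of in-memory \linkS4class{ImageStack} objects.
#' @param outCsv optional path; results are written as CSV.
#' @return data.frame with one row per image: \code{image_id},
#'   \code{status} and one column per scalar metric.
#' @export
batchRun <- function(config, manifest, outCsv = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  proc <- .PROCEDURES[[config$procedure]]
  if (is.null(proc))
    stop("unknown procedure '", config$procedure, "'; available: ",
         paste(names(.PROCEDURES), collapse = ", "))
  if (is.data.frame(manifest)) {
    ids <- manifest$image_id
    getters <- lapply(seq_len(nrow(manifest)), function(i) {
      function() {
        st <- readStack(manifest$path[i])
        rois <- if (!is.null(manifest$roi_path) &&
                    nzchar(manifest$roi_path[i]))
          readLabelImage(manifest$roi_path[i])
        else matrix(1L, dim(st@data)[1L], dim(st@data)[2L])
        list(stack = st, rois = rois)
      }
    })
  } else {
    ids <- names(manifest)
    getters <- lapply(manifest, function(st) function()
      list(stack = st,
           rois = matrix(1L, dim(st@data)[1L], dim(st@data)[2L])))
  }
  if (!length(ids)) {
    out <- data.frame(image_id = character(), status = character())
    if (!is.null(outCsv)) utils::write.csv(out, outCsv,
                                           row.names = FALSE)
    return(out)
  }
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows[[i]] <- tryCatch({
      inp <- getters[[i]]()
      res <- proc(inp$stack, inp$rois, config$params, ids[i])
      cbind(data.frame(image_id = ids[i], status = "ok"),
            as.data.frame(metrics(res)))
    }, error = function(e)
      data.frame(image_id = ids[i], status = paste0("error: ",
                                                    conditionMessage(e))))
  }
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  if (!is.null(outCsv))
    utils::write.csv(out, outCsv, row.names = FALSE)
  out
}
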