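# Formats, configuration and reproducibility plumbing. Stacks travel as
# multi-page TIFF (channels x z-planes as sequential 32-bit float
# pages) with voxel size, channel roles and the intensity scale
# recorded in a JSON sidecar (<path>.meta.json); ground truth as JSON;
# cohorts and result tables as CSV; configs as YAML. Coordinates in
# written tables are 0-based (z, y, x), origin at the first page's
# top-left.

#' Write an ImageStack as multi-page TIFF
#'
#' Pages are ordered channel-major (all z-planes of channel 1, then
#' channel 2, ...). Integer-valued intensities up to 65535 (the
#' realistic acquisition bit depth) are written as 16-bit samples and
#' round-trip bit-exactly; other data are written as 32-bit samples
#' after division by a power-of-two scale and round-trip to within
#' 1 part in 2^31 of full scale. The scale, sample type, voxel size,
#' shape and channel roles go to \code{<path>.meta.json}.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  d <- dim(stack@data)
  mx <- max(stack@data)
  uint16 <- mx <= 65535 && all(stack@data == round(stack@data))
  scale <- if (uint16) 65535
  else 2^max(0, ceiling(log2(max(mx, 1))))
  pages <- list()
  for (c in seq_len(d[4L]))
    for (z in seq_len(d[3L]))
      pages[[length(pages) + 1L]] <- stack@data[, , z, c] / scale
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (uint16) 16L else 32L)
  meta <- list(shape_zyx = c(d[3L], d[1L], d[2L]),
               voxel_size_um_zyx = voxelSize(stack),
               channels = channelNames(stack),
               intensity_scale = scale,
               sample_type = if (uint16) "uint16" else "quantized32",
               page_order = "channel_major")
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ImageStack written by writeStack
#'
#' @param path TIFF path; \code{<path>.meta.json} must exist unless
#'   both \code{voxelSize} and \code{channels} are overridden.
#' @param voxelSize optional (dz, dy, dx) override in um.
#' @param channels optional channel role override.
#' @return an \linkS4class{ImageStack}.
#' @export
readStack <- function(path, voxelSize = NULL, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  metaPath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE) else NULL
  vs <- voxelSize %||% meta$voxel_size_um_zyx
  if (is.null(vs))
    stop("voxel size unknown: no ", basename(metaPath),
         " sidecar (field voxel_size_um_zyx) and no voxelSize override")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- lapply(pages, dim)
  if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L)
    stop("inconsistent page shapes in ", path)
  chn <- channels %||% meta$channels %||% "channel1"
  nz <- length(pages) / length(chn)
  if (nz != round(nz))
    stop("page count ", length(pages),
         " is not a multiple of the channel count ", length(chn))
  scale <- meta$intensity_scale %||% 1
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  chans <- list()
  k <- 0L
  uint16 <- identical(meta$sample_type, "uint16")
  for (ch in chn) {
    vol <- array(0, c(ny, nx, nz))
    for (z in seq_len(nz)) {
      k <- k + 1L
      vol[, , z] <- if (uint16) round(pages[[k]] * scale)
      else pages[[k]] * scale
    }
    chans[[ch]] <- vol
  }
  ImageStack(chans, voxelSize = as.numeric(vs))
}

#' Write / read a binary mask as 8-bit TIFF (0/255)
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path TIFF path.
#' @export
writeMask <- function(mask, path) {
  m <- maskData(mask)
  pages <- lapply(seq_len(dim(m)[3L]), function(z)
    m[, , z] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeMask
#' @param voxelSize (dz, dy, dx) in um for the mask read back.
#' @export
readMask <- function(path, voxelSize = c(0.5, 0.2, 0.2)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  m <- array(FALSE, c(dim(pages[[1L]]), length(pages)))
  for (z in seq_along(pages)) m[, , z] <- pages[[z]] > 0.5
  BinaryMask(m, voxelSize = voxelSize,
             provenance = list(source = path))
}

#' Read a 2D integer label image (cell ROIs) from TIFF
#'
#' Labels are recovered from 16-bit grey levels (value * 65535).
#' @param path TIFF path.
#' @export
readLabelImage <- function(path) {
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' @rdname readLabelImage
#' @param labels integer matrix of cell labels.
#' @export
writeLabelImage <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read scene ground truth as JSON
#'
#' Object centres are written 0-based (z, y, x) alongside the ROI
#' label image.
#'
#' @param truth a \linkS4class{SceneTruth}.
#' @param path JSON path.
#' @export
writeTruth <- function(truth, path) {
  obj <- truthObjects(truth)
  obj$z <- obj$z - 1; obj$y <- obj$y - 1; obj$x <- obj$x - 1
  jsonlite::write_json(
    list(coordinate_convention = "0-based (z, y, x) voxel indices",
         objects = obj, cell_rois = cellRois(truth)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- as.data.frame(j$objects)
  obj$z <- obj$z + 1; obj$y <- obj$y + 1; obj$x <- obj$x + 1
  rois <- j$cell_rois
  new("SceneTruth", objects = obj,
      cellRois = matrix(as.integer(rois), nrow(rois), ncol(rois)))
}

#' Read / write a fraction-resolved qPCR cohort CSV
#'
#' Columns: sample_id, group, fraction, gene, ct.
#' @param path CSV path.
#' @export
readQpcrCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "group", "fraction", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("qPCR CSV lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname readQpcrCsv
#' @param records qPCR records data.frame.
#' @export
writeQpcrCsv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Procedure name plus its parameters (radii, sigmas, batch-frozen
#' thresholds, maxima tolerance, connectivity, size filters, channel
#' roles) and the seed every random step must draw from. Serializes
#' losslessly to YAML.
#'
#' @param procedure registered procedure name (see
#'   \code{\link{batchRun}}).
#' @param params named parameter list.
#' @param seed integer seed recorded with every run.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(procedure, params = list(), seed = 1L) {
  structure(list(procedure = procedure, params = params,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' @rdname runConfig
#' @param config a \code{RunConfig}.
#' @param path YAML path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  runConfig(x$procedure, x$params %||% list(), x$seed %||% 1L)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialization; changing any parameter
#' changes the hash.
#' @param config a \code{RunConfig}.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeRunConfig(config, f)
  unname(tools::md5sum(f))
}

#' Build a reproducibility log record for a run
#'
#' Records the package version, config hash, input-file hashes and the
#' seed. Identical configs and inputs give identical records, so logs
#' (like result tables) are byte-stable across reruns.
#'
#' @param config a \code{RunConfig}.
#' @param inputs character vector of input file paths.
#' @param logPath optional JSON path to write the record to.
#' @return the record, invisibly when written.
#' @export
runManifest <- function(config, inputs = character(),
                        logPath = NULL) {
  ih <- if (length(inputs)) {
    missing <- !file.exists(inputs)
    h <- rep(NA_character_, length(inputs))
    h[!missing] <- unname(tools::md5sum(inputs[!missing]))
    stats::setNames(h, basename(inputs))
  } else stats::setNames(character(), character())
  rec <- list(package = "mitoquant",
              version = as.character(utils::packageVersion("mitoquant")),
              procedure = config$procedure,
              config_hash = configHash(config),
              seed = config$seed,
              input_hashes = as.list(ih))
  if (!is.null(logPath)) {
    jsonlite::write_json(rec, logPath, auto_unbox = TRUE, digits = NA)
    return(invisible(rec))
  }
  rec
}
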