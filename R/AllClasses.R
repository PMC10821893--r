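#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib mitoquant, .registration = TRUE
NULL

#' Calibrated multi-channel 3D image stack
#'
#' Container for a multi-channel confocal z-stack. Voxel intensities are
#' stored as a 4D numeric array indexed \code{[y, x, z, channel]} with
#' channel names on the fourth dimension; all user-facing coordinate
#' tables report \code{(z, y, x)} voxel indices. Intensities are
#' non-negative finite reals regardless of on-disk integer type.
#'
#' @slot data 4D numeric array \code{[y, x, z, channel]}.
#' @slot voxelSize numeric(3), micrometres per voxel as \code{(dz, dy, dx)}.
#' @slot channelRoles character, role names, one per channel (e.g.
#'   \code{"mCherry"}, \code{"GFP"}, \code{"DNA"}, \code{"TOMM20"},
#'   \code{"DAPI"}).
#'
#' @aliases ImageStack
#' @exportClass ImageStack
setClass("ImageStack",
  representation(data = "array", voxelSize = "numeric",
                 channelRoles = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 4L)
      return("data must be a 4D array [y, x, z, channel]")
    if (any(!is.finite(d)) || any(d < 0))
      return("intensities must be finite and >= 0")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 strictly positive values (dz, dy, dx)")
    if (length(object@channelRoles) != dim(d)[4L])
      return("channelRoles must name every channel")
    if (anyDuplicated(object@channelRoles))
      return("channelRoles must be unique")
    TRUE
  })

#' Construct an ImageStack
#'
#' @param channels named list of 3D numeric arrays \code{[y, x, z]}, one
#'   per channel; names give the channel roles.
#' @param voxelSize micrometres per voxel, \code{(dz, dy, dx)}.
#' @return an \linkS4class{ImageStack}.
#' @examples
#' s <- ImageStack(list(mCherry = array(0, c(8, 8, 4)),
#'                      GFP = array(0, c(8, 8, 4))),
#'                 voxelSize = c(0.5, 0.2, 0.2))
#' channelNames(s)
#' @export
ImageStack <- function(channels, voxelSize = c(0.5, 0.2, 0.2)) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  dims <- dim(channels[[1L]])
  if (length(dims) == 2L) dims <- c(dims, 1L)
  arr <- array(0, c(dims, length(channels)),
               dimnames = list(NULL, NULL, NULL, names(channels)))
  for (i in seq_along(channels)) {
    ch <- channels[[i]]
    if (length(dim(ch)) == 2L) dim(ch) <- c(dim(ch), 1L)
    if (!identical(dim(ch), as.integer(dims)) &&
        !identical(dim(ch), dims))
      stop("all channels must share the same (y, x, z) shape")
    arr[, , , i] <- ch
  }
  new("ImageStack", data = arr, voxelSize = as.numeric(voxelSize),
      channelRoles = names(channels))
}

#' @describeIn ImageStack channel role names
#' @param x,object an \code{ImageStack}
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageStack-class
#' @export
setMethod("channelNames", "ImageStack", function(x) x@channelRoles)

#' @describeIn ImageStack voxel size in um, (dz, dy, dx)
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname ImageStack-class
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' Extract one channel as a 3D array
#'
#' @param x an \linkS4class{ImageStack}
#' @param channel channel role name
#' @return 3D numeric array \code{[y, x, z]}
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname getChannel
#' @export
setMethod("getChannel", "ImageStack", function(x, channel) {
  i <- match(channel, x@channelRoles)
  if (is.na(i))
    stop("unknown channel '", channel, "'; available: ",
         paste(x@channelRoles, collapse = ", "))
  ch <- x@data[, , , i, drop = FALSE]
  dim(ch) <- dim(x@data)[1:3]
  ch
})

#' Replace one channel of an ImageStack
#'
#' @param x an \linkS4class{ImageStack}
#' @param channel channel role name
#' @param value 3D numeric array of the stack's (y, x, z) shape
#' @export
setGeneric("setChannel", function(x, channel, value)
  standardGeneric("setChannel"))

#' @rdname setChannel
#' @export
setMethod("setChannel", "ImageStack", function(x, channel, value) {
  i <- match(channel, x@channelRoles)
  if (is.na(i)) stop("unknown channel '", channel, "'")
  if (length(dim(value)) == 2L) dim(value) <- c(dim(value), 1L)
  x@data[, , , i] <- value
  validObject(x)
  x
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack:", d[1L], "x", d[2L], "x", d[3L], "voxels (y x z),",
      d[4L], "channel(s)\n")
  cat("  channels :", paste(object@channelRoles, collapse = ", "), "\n")
  cat("  voxel um : dz =", object@voxelSize[1L],
      " dy =", object@voxelSize[2L], " dx =", object@voxelSize[3L], "\n")
})

#' Voxel-wise binary segmentation mask
#'
#' Logical 3D array plus the provenance of the threshold that produced
#' it, so a batch-frozen threshold can be audited and re-applied.
#'
#' @slot data logical 3D array \code{[y, x, z]}.
#' @slot voxelSize micrometres per voxel, \code{(dz, dy, dx)}.
#' @slot provenance list; typically \code{channel}, \code{threshold},
#'   \code{method}.
#' @aliases BinaryMask
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(data = "array", voxelSize = "numeric",
                 provenance = "list"),
  validity = function(object) {
    if (!is.logical(object@data) || length(dim(object@data)) != 3L)
      return("data must be a logical 3D array [y, x, z]")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 strictly positive values")
    TRUE
  })

#' Construct a BinaryMask
#' @param data logical 3D (or 2D, promoted to single-slice) array
#' @param voxelSize micrometres per voxel \code{(dz, dy, dx)}
#' @param provenance free-form provenance list
#' @export
BinaryMask <- function(data, voxelSize = c(0.5, 0.2, 0.2),
                       provenance = list()) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  new("BinaryMask", data = data, voxelSize = as.numeric(voxelSize),
      provenance = provenance)
}

#' @describeIn BinaryMask the logical voxel array
#' @param x,object a \code{BinaryMask}
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname BinaryMask-class
#' @export
setMethod("maskData", "BinaryMask", function(x) x@data)

#' @rdname BinaryMask-class
#' @export
setMethod("voxelSize", "BinaryMask", function(x) x@voxelSize)

#' @describeIn BinaryMask threshold provenance
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname BinaryMask-class
#' @export
setMethod("provenance", "BinaryMask", function(x) x@provenance)

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat("BinaryMask:", d[1L], "x", d[2L], "x", d[3L], "voxels,",
      sum(object@data), "member voxel(s)\n")
  if (length(object@provenance))
    cat("  provenance:",
        paste(names(object@provenance),
              vapply(object@provenance, function(v)
                paste(format(v), collapse = "/"), ""),
              sep = "=", collapse = ", "), "\n")
})

#' Planted-object registry of a synthetic scene
#'
#' Emitted by every scene generator; the acceptance oracle for the image
#' pipelines. Object centres are 1-based voxel indices \code{(z, y, x)}
#' in the accompanying stack; \code{cellRois} is a 2D integer label
#' image \code{[y, x]} tiling the field (0 never occurs: ROIs tile).
#'
#' @slot objects data.frame with columns \code{kind}, \code{z},
#'   \code{y}, \code{x}, \code{extent} (px) and, where applicable,
#'   \code{cell}.
#' @slot cellRois integer matrix \code{[y, x]} of cell labels.
#' @aliases SceneTruth
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(objects = "data.frame", cellRois = "matrix"),
  validity = function(object) {
    need <- c("kind", "z", "y", "x", "extent")
    if (!all(need %in% names(object@objects)))
      return(paste("objects must have columns",
                   paste(need, collapse = ", ")))
    TRUE
  })

#' @describeIn SceneTruth planted objects of one kind (or all)
#' @param x,object a \code{SceneTruth}
#' @param kind optional object kind filter
#' @export
setGeneric("truthObjects", function(x, kind = NULL)
  standardGeneric("truthObjects"))

#' @rdname SceneTruth-class
#' @export
setMethod("truthObjects", "SceneTruth", function(x, kind = NULL) {
  if (is.null(kind)) return(x@objects)
  x@objects[x@objects$kind %in% kind, , drop = FALSE]
})

#' @describeIn SceneTruth 2D cell-ROI label image
#' @export
setGeneric("cellRois", function(x) standardGeneric("cellRois"))

#' @rdname SceneTruth-class
#' @export
setMethod("cellRois", "SceneTruth", function(x) x@cellRois)

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth:", nrow(object@objects), "planted object(s)\n")
  if (nrow(object@objects))
    print(table(object@objects$kind))
})

#' Result of one quantification procedure on one image
#'
#' @slot imageId character identifier of the input image.
#' @slot procedure character name of the procedure run.
#' @slot metrics named list of scalar outputs (counts, volumes in um^3,
#'   MFIs, area fractions, overlap coefficients).
#' @slot params named list echoing every parameter needed to re-run.
#' @slot perCell data.frame of per-cell values (possibly empty).
#' @slot details list of non-scalar by-products (object tables, maxima
#'   coordinates) useful for auditing.
#' @aliases QuantResult
#' @exportClass QuantResult
setClass("QuantResult",
  representation(imageId = "character", procedure = "character",
                 metrics = "list", params = "list",
                 perCell = "data.frame", details = "list"),
  validity = function(object) {
    m <- object@metrics
    cnt <- m[grepl("^n_", names(m))]
    if (length(cnt) && any(vapply(cnt, function(v)
          v < 0 || v != round(v), logical(1))))
      return("counts must be non-negative integers")
    cf <- m[grepl("coefficient", names(m))]
    if (length(cf) && any(vapply(cf, function(v)
          v < -1e-12 || v > 1 + 1e-12, logical(1))))
      return("coefficients must lie in [0, 1]")
    TRUE
  })

QuantResult <- function(imageId, procedure, metrics, params,
                        perCell = data.frame(), details = list()) {
  new("QuantResult", imageId = as.character(imageId),
      procedure = procedure, metrics = metrics, params = params,
      perCell = perCell, details = details)
}

#' @describeIn QuantResult non-scalar by-products (object/maxima tables)
#' @export
setGeneric("resultDetails", function(x) standardGeneric("resultDetails"))

#' @rdname QuantResult-class
#' @export
setMethod("resultDetails", "QuantResult", function(x) x@details)

#' @describeIn QuantResult named list of scalar outputs
#' @param x,object a \code{QuantResult}
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname QuantResult-class
#' @export
setMethod("metrics", "QuantResult", function(x) x@metrics)

#' @describeIn QuantResult parameter echo sufficient to re-run
#' @export
setGeneric("paramsEcho", function(x) standardGeneric("paramsEcho"))

#' @rdname QuantResult-class
#' @export
setMethod("paramsEcho", "QuantResult", function(x) x@params)

#' @describeIn QuantResult per-cell breakdown (may be empty)
#' @export
setGeneric("perCell", function(x) standardGeneric("perCell"))

#' @rdname QuantResult-class
#' @export
setMethod("perCell", "QuantResult", function(x) x@perCell)

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult [", object@procedure, "] image:", object@imageId, "\n")
  for (nm in names(object@metrics))
    cat("  ", nm, "=", format(object@metrics[[nm]], digits = 6), "\n")
  if (nrow(object@perCell))
    cat("  per-cell rows:", nrow(object@perCell), "\n")
})

#' Outcome of a group comparison
#'
#' @slot testName character, the test actually run (records the route
#'   the normality-gated policy took).
#' @slot statistic named numeric test statistic(s).
#' @slot pValue numeric in [0, 1].
#' @slot descriptives data.frame with per-group \code{n}, \code{mean},
#'   \code{sem} (sem = sd/sqrt(n)).
#' @slot assumptions list of assumption flags (per-group normality,
#'   homoscedasticity, and the alpha used).
#' @slot posthoc data.frame of pairwise comparisons (factorial designs).
#' @aliases StatResult
#' @exportClass StatResult
setClass("StatResult",
  representation(testName = "character", statistic = "numeric",
                 pValue = "numeric", descriptives = "data.frame",
                 assumptions = "list", posthoc = "data.frame"),
  validity = function(object) {
    if (length(object@pValue) != 1L || is.na(object@pValue) ||
        object@pValue < 0 || object@pValue > 1)
      return("pValue must be a single value in [0, 1]")
    TRUE
  })

StatResult <- function(testName, statistic, pValue, descriptives,
                       assumptions = list(), posthoc = data.frame()) {
  new("StatResult", testName = testName, statistic = statistic,
      pValue = as.numeric(pValue), descriptives = descriptives,
      assumptions = assumptions, posthoc = posthoc)
}

#' @describeIn StatResult the p value
#' @param x,object a \code{StatResult}
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname StatResult-class
#' @export
setMethod("pValue", "StatResult", function(x) x@pValue)

#' @describeIn StatResult name of the test that was run
#' @export
setGeneric("testName", function(x) standardGeneric("testName"))

#' @rdname StatResult-class
#' @export
setMethod("testName", "StatResult", function(x) x@testName)

#' @describeIn StatResult per-group n, mean, sem
#' @export
setGeneric("descriptives", function(x) standardGeneric("descriptives"))

#' @rdname StatResult-class
#' @export
setMethod("descriptives", "StatResult", function(x) x@descriptives)

#' @describeIn StatResult post-hoc pairwise table
#' @export
setGeneric("posthocTable", function(x) standardGeneric("posthocTable"))

#' @rdname StatResult-class
#' @export
setMethod("posthocTable", "StatResult", function(x) x@posthoc)

setMethod("show", "StatResult", function(object) {
  cat("StatResult:", object@testName, "\n")
  cat("  statistic:", paste(names(object@statistic), "=",
                            format(object@statistic, digits = 6),
                            collapse = ", "), "\n")
  cat("  p value  :", format(object@pValue, digits = 6), "\n")
  print(object@descriptives, row.names = FALSE)
  if (nrow(object@posthoc)) {
    cat("  post-hoc:\n")
    print(object@posthoc, row.names = FALSE)
  }
})
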