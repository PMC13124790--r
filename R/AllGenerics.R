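#' @name accessors
#' @title Accessors for cmrmotus containers
#' @param x a cmrmotus object.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("frameCount", function(x, ...) standardGeneric("frameCount"))
#' @rdname accessors
#' @export
setGeneric("coilCount", function(x, ...) standardGeneric("coilCount"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x, ...) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("referenceImages", function(x, ...)
  standardGeneric("referenceImages"))
#' @rdname accessors
#' @export
setGeneric("lowRankPart", function(x, ...) standardGeneric("lowRankPart"))
#' @rdname accessors
#' @export
setGeneric("sparsePart", function(x, ...) standardGeneric("sparsePart"))
#' @rdname accessors
#' @export
setGeneric("cineImages", function(x, ...) standardGeneric("cineImages"))
#' @rdname accessors
#' @export
setGeneric("motionFields", function(x, ...) standardGeneric("motionFields"))

setMethod("nVoxels", "ImageGrid", function(x, ...) x@nx * x@ny)
setMethod("frameCount", "DynamicKSpace", function(x, ...) length(x@samp))
setMethod("frameCount", "ReferenceSeries", function(x, ...) ncol(x@L))
setMethod("frameCount", "CineSeries", function(x, ...) ncol(x@H))
setMethod("frameCount", "MotionFieldStack", function(x, ...) dim(x@D)[4])
setMethod("frameCount", "LowRankMotionModel", function(x, ...) x@frames)
setMethod("frameCount", "PhantomTruth", function(x, ...) ncol(x@frames))
setMethod("coilCount", "DynamicKSpace", function(x, ...) x@nCoils)
setMethod("coilCount", "CoilMaps", function(x, ...) dim(x@maps)[3])
setMethod("referenceImages", "ReferenceSeries", function(x, ...) x@L + x@S)
setMethod("lowRankPart", "ReferenceSeries", function(x, ...) x@L)
setMethod("sparsePart", "ReferenceSeries", function(x, ...) x@S)
setMethod("cineImages", "CineSeries", function(x, ...) x@H)
setMethod("motionFields", "MotionFieldStack", function(x, ...) x@D)

#' k-space coordinates of the sampled locations of one frame
#'
#' Returns the sampled k-space coordinates in cycles/FOV in [-N/2, N/2),
#' matching the sample ordering of the stored data (kx fastest for
#' Cartesian lines).
#'
#' @param x a [DynamicKSpace-class].
#' @param frame frame index (1-based).
#' @return numeric matrix (samples x 2) with columns kx, ky.
#' @export
kSpaceCoordinates <- function(x, frame = 1L) {
  stopifnot(is(x, "DynamicKSpace"))
  nx <- x@grid@nx; ny <- x@grid@ny
  tofreq <- function(bin, n) ifelse(bin >= n / 2, bin - n, bin)  # 0-based bin
  if (x@scheme == "cartesian-lines") {
    ky <- tofreq(x@samp[[frame]] - 1L, ny)
    kx <- tofreq(0:(nx - 1L), nx)
    cbind(kx = rep(kx, times = length(ky)), ky = rep(ky, each = nx))
  } else {
    idx <- x@samp[[frame]] - 1L
    cbind(kx = tofreq(idx %% nx, nx), ky = tofreq(idx %/% nx, ny))
  }
}

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %d x %d voxels, %.3g x %.3g mm\n",
              object@nx, object@ny, object@dx, object@dy))
})

setMethod("show", "DynamicKSpace", function(object) {
  ns <- vapply(object@samples, nrow, 1L)
  cat(sprintf("DynamicKSpace: %d frames, %d coils, %s sampling\n",
              frameCount(object), object@nCoils, object@scheme))
  cat(sprintf("  grid %d x %d; %d-%d samples/frame (acceleration ~%.1f)\n",
              object@grid@nx, object@grid@ny, min(ns), max(ns),
              nVoxels(object@grid) / mean(ns)))
})

setMethod("show", "CoilMaps", function(object) {
  cat(sprintf("CoilMaps: %d coils on %d x %d grid\n",
              coilCount(object), object@grid@nx, object@grid@ny))
})

setMethod("show", "ReferenceSeries", function(object) {
  cat(sprintf("ReferenceSeries (Q = L + S): %d voxels x %d frames\n",
              nrow(object@L), ncol(object@L)))
})

setMethod("show", "CineSeries", function(object) {
  cat(sprintf("CineSeries: %d voxels x %d frames\n",
              nrow(object@H), ncol(object@H)))
})

setMethod("show", "MotionFieldStack", function(object) {
  d <- object@D
  cat(sprintf("MotionFieldStack: %d x %d x %d frames; |D| max %.3g voxels\n",
              dim(d)[1], dim(d)[2], dim(d)[4], max(abs(d))))
})

setMethod("show", "LowRankMotionModel", function(object) {
  cat(sprintf(
    "LowRankMotionModel: rank %d, %d x %d spatial control points, %s\n",
    object@rank, object@ctrl[1], object@ctrl[2],
    if (object@temporalBasis == "bspline")
      sprintf("%d temporal control points", object@ctrlT)
    else "dense temporal coefficients"))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d x %d, %d frames at %.0f ms; peak |D| %.2f voxels\n",
    object@config@nx, object@config@ny, frameCount(object),
    object@config@dt * 1000, max(abs(object@motion@D))))
})

setMethod("show", "ReconConfig", function(object) {
  cat(sprintf(
    "ReconConfig: lambdaS=%g lambdaTV=%g rankL=%s rankD=%d ctrl=%dx%d%s\n",
    object@lambdaS, object@lambdaTV,
    if (is.na(object@rankL)) sprintf("nuclear(%g)", object@lambdaL)
    else object@rankL,
    object@rankD, object@ctrlX, object@ctrlY,
    if (is.na(object@ctrlT)) "" else sprintf(" ctrlT=%d", object@ctrlT)))
  cat(sprintf("  %d alternations, <=%d/%d inner iterations, seed %d\n",
              object@alternations, object@maxIterLps, object@maxIterMotion,
              object@seed))
})
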