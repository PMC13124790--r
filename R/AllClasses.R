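#' Image grid geometry
#'
#' A 2D reconstruction grid. Coordinates are voxel-centered and 0-based with
#' x along the first array dimension and y along the second; displacements
#' are expressed in voxel units throughout the package.
#'
#' @slot nx,ny integer voxel counts (at least 8 each).
#' @slot dx,dy voxel spacing in mm.
#' @slot origin coordinate convention tag (fixed).
#' @export
setClass("ImageGrid",
  representation(nx = "integer", ny = "integer",
                 dx = "numeric", dy = "numeric", origin = "character"),
  prototype(dx = 1, dy = 1, origin = "voxel-centered-0-based"))

setValidity("ImageGrid", function(object) {
  if (length(object@nx) != 1L || length(object@ny) != 1L)
    return("nx and ny must be scalars")
  if (object@nx < 8L || object@ny < 8L) return("nx and ny must be >= 8")
  if (object@dx <= 0 || object@dy <= 0) return("voxel spacings must be > 0")
  TRUE
})

#' @param nx,ny voxel counts.
#' @param dx,dy voxel spacing (mm).
#' @rdname ImageGrid-class
#' @export
ImageGrid <- function(nx, ny, dx = 1, dy = 1) {
  new("ImageGrid", nx = as.integer(nx), ny = as.integer(ny),
      dx = as.numeric(dx), dy = as.numeric(dy))
}

#' Multi-coil dynamic k-space
#'
#' Per-frame sampled k-space for a dynamic acquisition. Two sampling schemes
#' are supported: `"cartesian-lines"` stores, per frame, the sampled ky line
#' indices (1-based frequency bins; full kx readouts, kx fastest in the sample
#' ordering), and `"gridded-points"` stores explicit 1-based linear indices
#' into the nx-by-ny k-space grid (used for golden-angle radial data after
#' gridding). Sample values are complex matrices with one row per sample and
#' one column per coil. k-space coordinates are in cycles/FOV in
#' [-N/2, N/2); see [kSpaceCoordinates()].
#'
#' @slot grid an [ImageGrid-class].
#' @slot nCoils integer coil count.
#' @slot scheme `"cartesian-lines"` or `"gridded-points"`.
#' @slot samp list (length = frames) of integer vectors: ky lines or linear
#'   k-grid indices.
#' @slot samples list of complex matrices (samples x coils).
#' @export
setClass("DynamicKSpace",
  representation(grid = "ImageGrid", nCoils = "integer", scheme = "character",
                 samp = "list", samples = "list"))

setValidity("DynamicKSpace", function(object) {
  M <- length(object@samp)
  if (M < 1L) return("at least one frame required")
  if (length(object@samples) != M) return("samp/samples length mismatch")
  if (object@nCoils < 1L) return("coil count must be >= 1")
  if (!object@scheme %in% c("cartesian-lines", "gridded-points"))
    return("unknown sampling scheme")
  nx <- object@grid@nx; ny <- object@grid@ny
  for (t in seq_len(M)) {
    v <- object@samp[[t]]
    if (length(v) < 1L) return(sprintf("frame %d has no samples", t))
    if (object@scheme == "cartesian-lines") {
      if (any(v < 1L | v > ny)) return("ky line index outside grid")
      nexp <- nx * length(v)
    } else {
      if (any(v < 1L | v > nx * ny)) return("k-space index outside grid")
      nexp <- length(v)
    }
    s <- object@samples[[t]]
    if (!is.matrix(s) || nrow(s) != nexp || ncol(s) != object@nCoils)
      return(sprintf("frame %d: sample matrix must be %d x %d", t, nexp,
                     object@nCoils))
    if (!all(is.finite(Re(s))) || !all(is.finite(Im(s))))
      return("k-space samples contain NaN/Inf")
  }
  TRUE
})

#' @param grid an [ImageGrid-class].
#' @param samp list of per-frame integer vectors (ky lines or linear indices).
#' @param samples list of complex (samples x coils) matrices.
#' @param scheme sampling scheme.
#' @rdname DynamicKSpace-class
#' @export
DynamicKSpace <- function(grid, samp, samples,
                          scheme = c("cartesian-lines", "gridded-points")) {
  scheme <- match.arg(scheme)
  nCoils <- if (length(samples)) ncol(samples[[1]]) else 0L
  samples <- lapply(samples, function(s) {
    storage.mode(s) <- "complex"
    s
  })
  new("DynamicKSpace", grid = grid, nCoils = as.integer(nCoils),
      scheme = scheme, samp = lapply(samp, as.integer), samples = samples)
}

#' Static coil sensitivity maps
#'
#' Complex sensitivities per coil on the image grid; assumed static over the
#' whole acquisition, so a single reference image is warped before the coil
#' weighting is applied.
#'
#' @slot maps complex array (nx, ny, coils).
#' @slot grid an [ImageGrid-class].
#' @export
setClass("CoilMaps",
  representation(maps = "array", grid = "ImageGrid"))

setValidity("CoilMaps", function(object) {
  d <- dim(object@maps)
  if (length(d) != 3L) return("maps must be an nx x ny x coils array")
  if (d[1] != object@grid@nx || d[2] != object@grid@ny)
    return("maps do not match the grid")
  if (d[3] < 1L) return("coil count must be >= 1")
  if (!all(is.finite(Re(object@maps))) || !all(is.finite(Im(object@maps))))
    return("coil maps contain NaN/Inf")
  TRUE
})

#' @param maps complex (nx, ny, coils) array.
#' @param grid an [ImageGrid-class].
#' @rdname CoilMaps-class
#' @export
CoilMaps <- function(maps, grid) {
  storage.mode(maps) <- "complex"
  new("CoilMaps", maps = maps, grid = grid)
}

#' Contrast-varying reference series Q = L + S
#'
#' The motion-static, contrast-varying reference images as a low-rank plus
#' sparse decomposition on the Casorati matrix (voxels x frames). The
#' reference series itself is always `Q = L + S` by construction; use
#' [referenceImages()].
#'
#' @slot L,S complex matrices (voxels x frames).
#' @slot grid an [ImageGrid-class].
#' @export
setClass("ReferenceSeries",
  representation(L = "matrix", S = "matrix", grid = "ImageGrid"))

setValidity("ReferenceSeries", function(object) {
  if (!identical(dim(object@L), dim(object@S))) return("L/S shape mismatch")
  if (nrow(object@L) != object@grid@nx * object@grid@ny)
    return("voxel count does not match the grid")
  for (nm in c("L", "S")) {
    x <- slot(object, nm)
    if (!all(is.finite(Re(x))) || !all(is.finite(Im(x))))
      return(paste(nm, "contains NaN/Inf"))
  }
  TRUE
})

#' @param L,S complex (voxels x frames) matrices.
#' @param grid an [ImageGrid-class].
#' @rdname ReferenceSeries-class
#' @export
ReferenceSeries <- function(L, S, grid) {
  storage.mode(L) <- "complex"; storage.mode(S) <- "complex"
  new("ReferenceSeries", L = L, S = S, grid = grid)
}

#' Motion-resolved cine series
#'
#' The target cine `H`, obtained by warping each reference frame with its
#' motion field: `h_t = warp(q_t, D_t)`.
#'
#' @slot H complex matrix (voxels x frames).
#' @slot grid an [ImageGrid-class].
#' @export
setClass("CineSeries",
  representation(H = "matrix", grid = "ImageGrid"))

setValidity("CineSeries", function(object) {
  if (nrow(object@H) != object@grid@nx * object@grid@ny)
    return("voxel count does not match the grid")
  if (!all(is.finite(Re(object@H))) || !all(is.finite(Im(object@H))))
    return("H contains NaN/Inf")
  TRUE
})

#' @param H complex (voxels x frames) matrix.
#' @param grid an [ImageGrid-class].
#' @rdname CineSeries-class
#' @export
CineSeries <- function(H, grid) {
  storage.mode(H) <- "complex"
  new("CineSeries", H = H, grid = grid)
}

#' Dense displacement field stack
#'
#' Pull-back displacement fields in voxel units: the cine value at voxel r is
#' obtained by sampling the reference at `r + D_t(r)`. Component 1 of the
#' third dimension is the x-displacement (first array dimension), component 2
#' the y-displacement.
#'
#' @slot D numeric array (nx, ny, 2, frames).
#' @slot grid an [ImageGrid-class].
#' @export
setClass("MotionFieldStack",
  representation(D = "array", grid = "ImageGrid"))

setValidity("MotionFieldStack", function(object) {
  d <- dim(object@D)
  if (length(d) != 4L || d[3] != 2L)
    return("D must be an (nx, ny, 2, frames) array")
  if (d[1] != object@grid@nx || d[2] != object@grid@ny)
    return("D does not match the grid")
  if (!all(is.finite(object@D))) return("D contains NaN/Inf")
  TRUE
})

#' @param D numeric (nx, ny, 2, frames) array, voxel units.
#' @param grid an [ImageGrid-class].
#' @rdname MotionFieldStack-class
#' @export
MotionFieldStack <- function(D, grid) {
  storage.mode(D) <- "double"
  new("MotionFieldStack", D = D, grid = grid)
}

#' Explicit-rank B-spline motion model
#'
#' Low-rank motion model `D ~ Phi Psi^T` on cubic B-spline control grids:
#' `phi` holds the spatial coefficients (x-block stacked on y-block, one
#' column per rank component) on an ncx-by-ncy control grid, `psi` the
#' temporal coefficients, either on an nct control grid
#' (`temporalBasis = "bspline"`) or one row per frame
#' (`temporalBasis = "identity"`).
#'
#' @slot rank explicit rank (number of components).
#' @slot phi numeric matrix (2 * ncx * ncy, rank).
#' @slot psi numeric matrix (nct or frames, rank).
#' @slot ctrl integer c(ncx, ncy) spatial control-point counts.
#' @slot ctrlT integer temporal control-point count (NA when identity).
#' @slot temporalBasis `"bspline"` or `"identity"`.
#' @slot frames integer frame count M.
#' @slot grid an [ImageGrid-class].
#' @export
setClass("LowRankMotionModel",
  representation(rank = "integer", phi = "matrix", psi = "matrix",
                 ctrl = "integer", ctrlT = "integer",
                 temporalBasis = "character", frames = "integer",
                 grid = "ImageGrid"))

setValidity("LowRankMotionModel", function(object) {
  if (object@rank < 1L) return("rank must be >= 1")
  if (any(object@ctrl < 4L)) return("need >= 4 spatial control points")
  if (object@ctrl[1] > object@grid@nx || object@ctrl[2] > object@grid@ny)
    return("control grid exceeds image grid")
  if (!identical(dim(object@phi),
                 c(2L * object@ctrl[1] * object@ctrl[2], object@rank)))
    return("phi has the wrong shape")
  if (object@temporalBasis == "bspline") {
    if (is.na(object@ctrlT) || object@ctrlT < 4L)
      return("need >= 4 temporal control points")
    if (object@ctrlT > object@frames)
      return("temporal control grid exceeds frame count")
    nt <- object@ctrlT
  } else if (object@temporalBasis == "identity") {
    nt <- object@frames
  } else return("unknown temporal basis")
  if (!identical(dim(object@psi), c(nt, object@rank)))
    return("psi has the wrong shape")
  if (!all(is.finite(object@phi)) || !all(is.finite(object@psi)))
    return("coefficients contain NaN/Inf")
  TRUE
})

#' @param phi,psi coefficient matrices (see slots).
#' @param ctrl spatial control counts c(ncx, ncy) (scalar recycled).
#' @param ctrlT temporal control count or NA for one coefficient per frame.
#' @param frames frame count M.
#' @param grid an [ImageGrid-class].
#' @rdname LowRankMotionModel-class
#' @export
LowRankMotionModel <- function(phi, psi, ctrl, frames, grid, ctrlT = NA) {
  ctrl <- as.integer(rep(ctrl, length.out = 2))
  new("LowRankMotionModel", rank = ncol(phi), phi = phi, psi = psi,
      ctrl = ctrl, ctrlT = as.integer(ctrlT),
      temporalBasis = if (is.na(ctrlT)) "identity" else "bspline",
      frames = as.integer(frames), grid = grid)
}

#' Reconstruction configuration
#'
#' All weights, ranks, control grids, iteration budgets and seeds of the
#' alternating reconstruction. Defaults follow the reference implementation
#' choices: 5 alternations, 60 inner iterations for the motion step, the
#' image step stops when the normalized objective change stays below 1e-4
#' over 4 consecutive iterations, and the gradient step size is 1.3/gamma
#' with gamma the largest eigenvalue of F F* from a power method.
#'
#' @slot lambdaL nuclear-norm weight (ignored when `rankL` is set).
#' @slot lambdaS temporal-Fourier sparsity weight.
#' @slot lambdaTV motion total-variation weight.
#' @slot rankL explicit rank of L (NA = soft nuclear-norm thresholding).
#' @slot rankD explicit rank of the motion model.
#' @slot ctrlX,ctrlY spatial B-spline control-point counts.
#' @slot ctrlT temporal control-point count (NA = one coefficient per frame).
#' @slot alternations outer alternation count.
#' @slot maxIterLps,maxIterMotion inner iteration caps for steps 1 and 2.
#' @slot tol,tolIters step-1 stopping rule (relative change, streak length).
#' @slot stepFactor FISTA step size = stepFactor / gamma.
#' @slot powerTol,powerMaxIter power-method controls for gamma.
#' @slot normalizeData rescale k-space so the time-averaged zero-filled
#'   image has a fixed maximum magnitude (makes the preset lambdas
#'   meaningful across datasets; see the methods vignette).
#' @slot tvVariant `"mixed"` (componentwise-isotropic 2,1 norm) or
#'   `"printed"` (root of squared per-component sums).
#' @slot seed integer seed controlling all randomness.
#' @export
setClass("ReconConfig",
  representation(lambdaL = "numeric", lambdaS = "numeric",
                 lambdaTV = "numeric", rankL = "integer", rankD = "integer",
                 ctrlX = "integer", ctrlY = "integer", ctrlT = "integer",
                 alternations = "integer", maxIterLps = "integer",
                 maxIterMotion = "integer", tol = "numeric",
                 tolIters = "integer", stepFactor = "numeric",
                 powerTol = "numeric", powerMaxIter = "integer",
                 normalizeData = "logical", tvVariant = "character",
                 seed = "integer"),
  prototype(lambdaL = 0, lambdaS = 1, lambdaTV = 1e-8, rankL = 1L,
            rankD = 1L, ctrlX = 16L, ctrlY = 16L, ctrlT = NA_integer_,
            alternations = 5L, maxIterLps = 100L, maxIterMotion = 60L,
            tol = 1e-4, tolIters = 4L, stepFactor = 1.3, powerTol = 1e-3,
            powerMaxIter = 100L, normalizeData = TRUE, tvVariant = "mixed",
            seed = 1L))

setValidity("ReconConfig", function(object) {
  if (object@lambdaL < 0 || object@lambdaS < 0 || object@lambdaTV < 0)
    return("regularization weights must be >= 0")
  if (!is.na(object@rankL) && object@rankL < 1L) return("rankL must be >= 1")
  if (object@rankD < 1L) return("rankD must be >= 1")
  if (object@ctrlX < 4L || object@ctrlY < 4L)
    return("need >= 4 control points per spatial direction")
  if (!is.na(object@ctrlT) && object@ctrlT < 4L)
    return("need >= 4 temporal control points")
  if (object@alternations < 0L) return("alternations must be >= 0")
  if (object@maxIterLps < 1L || object@maxIterMotion < 1L)
    return("iteration caps must be >= 1")
  if (object@tol <= 0 || object@tolIters < 1L) return("invalid tolerance")
  if (object@stepFactor <= 0) return("step factor must be > 0")
  if (!object@tvVariant %in% c("mixed", "printed"))
    return("tvVariant must be 'mixed' or 'printed'")
  TRUE
})

#' @param ... slot values overriding the defaults (see slots).
#' @rdname ReconConfig-class
#' @export
ReconConfig <- function(...) {
  args <- list(...)
  intSlots <- c("rankL", "rankD", "ctrlX", "ctrlY", "ctrlT", "alternations",
                "maxIterLps", "maxIterMotion", "tolIters", "powerMaxIter",
                "seed")
  for (nm in intersect(names(args), intSlots))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("ReconConfig"), args))
}

#' Phantom configuration
#'
#' Acquisition and anatomy parameters of the analytic short-axis first-pass
#' perfusion phantom. The defaults emulate a saturation-recovery gradient-echo
#' perfusion acquisition: 600 frames at 50 ms (1 s heart cycle), 100 x 100
#' matrix, Tsat = 150 ms, flip = 15 degrees, TR = 2 ms, 8 coils, and
#' pseudo-random Cartesian sampling with 12 readouts per frame.
#'
#' @slot frames,dt frame count and frame interval (s).
#' @slot nx,ny matrix size.
#' @slot heartPeriod cardiac period (s).
#' @slot TR,Tsat repetition time and saturation delay (s).
#' @slot flip flip angle (degrees, in (0, 90]).
#' @slot nCoils coil count.
#' @slot cardiacContraction peak fractional radial stretch of the backward
#'   cardiac map (dimensionless; 0 disables cardiac motion).
#' @slot respAmplitude,respPeriod sinusoidal translation amplitude (voxels,
#'   along y) and period (s); 0 disables respiration.
#' @slot bulkShift,bulkOnset step translation (voxels, x/y) applied from
#'   `bulkOnset` seconds onward (Inf disables).
#' @slot rvOnset,lvOnset,myoOnset gamma-variate bolus onsets (s).
#' @slot bolusShape,bolusScale gamma-variate shape alpha and scale beta (s).
#' @slot peakConc peak concentrations (mmol/L), named rv/lv/myo.
#' @slot r1 contrast agent relaxivity (L mmol^-1 s^-1).
#' @slot t1Blood,t1Myo,t1Body baseline T1 (s).
#' @slot m0 equilibrium magnetization, named body/myo/blood.
#' @slot scheme sampling scheme.
#' @slot readouts readouts (Cartesian lines) or spokes per frame.
#' @slot centerLines fully sampled central ky lines per frame (Cartesian).
#' @slot noiseSigma complex noise SD per k-space sample (NA = set for about
#'   30 dB SNR on the time-averaged image).
#' @slot seed integer seed.
#' @export
setClass("PhantomConfig",
  representation(frames = "integer", dt = "numeric", nx = "integer",
                 ny = "integer", heartPeriod = "numeric", TR = "numeric",
                 Tsat = "numeric", flip = "numeric", nCoils = "integer",
                 cardiacContraction = "numeric", respAmplitude = "numeric",
                 respPeriod = "numeric", bulkShift = "numeric",
                 bulkOnset = "numeric", rvOnset = "numeric",
                 lvOnset = "numeric", myoOnset = "numeric",
                 bolusShape = "numeric", bolusScale = "numeric",
                 peakConc = "numeric", r1 = "numeric", t1Blood = "numeric",
                 t1Myo = "numeric", t1Body = "numeric", m0 = "numeric",
                 scheme = "character", readouts = "integer",
                 centerLines = "integer", noiseSigma = "numeric",
                 seed = "integer"),
  prototype(frames = 600L, dt = 0.05, nx = 100L, ny = 100L, heartPeriod = 1,
            TR = 0.002, Tsat = 0.150, flip = 15, nCoils = 8L,
            cardiacContraction = 0.35, respAmplitude = 0, respPeriod = 4,
            bulkShift = c(0, 0), bulkOnset = Inf, rvOnset = 5, lvOnset = 8,
            myoOnset = 12, bolusShape = 3, bolusScale = 1.5,
            peakConc = c(rv = 8, lv = 6, myo = 1.2), r1 = 5.0,
            t1Blood = 1.650, t1Myo = 1.100, t1Body = 0.900,
            m0 = c(body = 0.8, myo = 0.9, blood = 1.0),
            scheme = "cartesian_pseudorandom", readouts = 12L,
            centerLines = 4L, noiseSigma = NA_real_, seed = 1L))

setValidity("PhantomConfig", function(object) {
  if (object@frames < 1L) return("frame count must be >= 1")
  if (object@dt <= 0 || object@heartPeriod <= 0 || object@respPeriod <= 0)
    return("periods must be > 0")
  if (object@TR <= 0 || object@Tsat <= 0) return("TR and Tsat must be > 0")
  if (object@flip <= 0 || object@flip > 90)
    return("flip angle must be in (0, 90] degrees")
  if (object@nCoils < 1L) return("coil count must be >= 1")
  if (object@nx < 16L || object@ny < 16L) return("matrix must be >= 16")
  if (object@bolusShape <= 0 || object@bolusScale <= 0)
    return("gamma-variate shape and scale must be > 0")
  if (any(object@peakConc < 0)) return("peak concentrations must be >= 0")
  if (!all(c("rv", "lv", "myo") %in% names(object@peakConc)))
    return("peakConc must be named rv/lv/myo")
  if (!all(c("body", "myo", "blood") %in% names(object@m0)))
    return("m0 must be named body/myo/blood")
  if (object@t1Blood <= 0 || object@t1Myo <= 0 || object@t1Body <= 0)
    return("baseline T1 must be > 0")
  if (!object@scheme %in% c("cartesian_pseudorandom", "radial_golden_angle"))
    return("unknown sampling scheme")
  if (object@readouts < 1L) return("readouts must be >= 1")
  if (!is.na(object@noiseSigma) && object@noiseSigma < 0)
    return("noise sigma must be >= 0")
  TRUE
})

#' @param ... slot values overriding the defaults (see slots).
#' @rdname PhantomConfig-class
#' @export
PhantomConfig <- function(...) {
  args <- list(...)
  intSlots <- c("frames", "nx", "ny", "nCoils", "readouts", "centerLines",
                "seed")
  for (nm in intersect(names(args), intSlots))
    args[[nm]] <- as.integer(args[[nm]])
  if (!is.null(args$noiseSigma)) args$noiseSigma <- as.numeric(args$noiseSigma)
  do.call(new, c(list("PhantomConfig"), args))
}

#' Phantom ground truth
#'
#' Noiseless coil-combined frames, the matching motion-static reference
#' frames (contrast on, motion off), exact analytic pull-back motion fields,
#' per-frame compartment label maps and the compartment enhancement curves.
#' Label codes: 0 background, 1 body, 2 myocardium, 3 LV blood, 4 RV blood.
#'
#' @slot frames real matrix (voxels x frames), noiseless moving frames.
#' @slot refFrames real matrix (voxels x frames), motion-static references.
#' @slot motion a [MotionFieldStack-class] (exact, frame-0 referenced).
#' @slot labels integer array (nx, ny, frames).
#' @slot curves concentration curves, matrix (frames x 3) named rv/lv/myo.
#' @slot config the generating [PhantomConfig-class].
#' @export
setClass("PhantomTruth",
  representation(frames = "matrix", refFrames = "matrix",
                 motion = "MotionFieldStack", labels = "array",
                 curves = "matrix", config = "PhantomConfig"))

setValidity("PhantomTruth", function(object) {
  if (!all(is.finite(object@frames)) || !all(is.finite(object@refFrames)))
    return("frames contain NaN/Inf")
  if (any(object@curves < 0)) return("enhancement curves must be >= 0")
  TRUE
})
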