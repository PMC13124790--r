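#' @importFrom Matrix sparseMatrix Diagonal
NULL

# 1D cubic free-form-deformation basis on [0, n-1] with nc control points.
# Control spacing h = (n-1)/(nc-3); a position maps to local coordinate
# t in [0,1] within a knot cell and is influenced by 4 consecutive control
# points. Returns a sparse n x nc matrix.
.ffdBasis <- function(n, nc) {
  if (nc < 4L) stop("need at least 4 control points")
  if (nc > n) stop("control grid exceeds image grid")
  h <- (n - 1) / (nc - 3)
  u <- (0:(n - 1)) / h
  i0 <- pmin(floor(u), nc - 4)
  tt <- u - i0
  w <- cbind((1 - tt)^3 / 6,
             (3 * tt^3 - 6 * tt^2 + 4) / 6,
             (-3 * tt^3 + 3 * tt^2 + 3 * tt + 1) / 6,
             tt^3 / 6)
  Matrix::sparseMatrix(i = rep(seq_len(n), 4L),
                       j = as.vector(i0 + rep(1:4, each = n)),
                       x = as.vector(w), dims = c(n, nc))
}

# spatial (voxels x controls) and temporal (frames x controls) basis matrices
.motionBases <- function(model) {
  Bx <- .ffdBasis(model@grid@nx, model@ctrl[1])
  By <- .ffdBasis(model@grid@ny, model@ctrl[2])
  Bs <- kronecker(By, Bx)  # voxel index runs x-fastest, control x-fastest
  Bt <- if (model@temporalBasis == "bspline")
    .ffdBasis(model@frames, model@ctrlT)
  else Matrix::Diagonal(model@frames)
  list(Bs = Bs, Bt = Bt)
}

# dense displacement cubes from coefficients; bases may be precomputed
.expandMotionCubes <- function(model, bases = NULL) {
  if (is.null(bases)) bases <- .motionBases(model)
  nx <- model@grid@nx; ny <- model@grid@ny
  ncs <- model@ctrl[1] * model@ctrl[2]
  psiD <- as.matrix(bases$Bt %*% model@psi)              # frames x rank
  dx <- as.matrix(bases$Bs %*% model@phi[seq_len(ncs), , drop = FALSE] %*%
                    t(psiD))
  dy <- as.matrix(bases$Bs %*% model@phi[ncs + seq_len(ncs), , drop = FALSE] %*%
                    t(psiD))
  list(dx = array(dx, c(nx, ny, model@frames)),
       dy = array(dy, c(nx, ny, model@frames)))
}

#' Expand a low-rank B-spline motion model to dense displacement fields
#'
#' Evaluates `D = (B_s Phi) (B_t Psi)^T` on the voxel grid: cubic
#' tensor-product B-spline bases in space, and either a cubic B-spline basis
#' or the identity in time. The expansion is linear in `phi` and in `psi`
#' separately.
#'
#' @param model a [LowRankMotionModel-class].
#' @return a [MotionFieldStack-class] (voxel units).
#' @export
expandMotion <- function(model) {
  stopifnot(is(model, "LowRankMotionModel"))
  cubes <- .expandMotionCubes(model)
  D <- array(0, c(model@grid@nx, model@grid@ny, 2L, model@frames))
  D[, , 1L, ] <- cubes$dx
  D[, , 2L, ] <- cubes$dy
  MotionFieldStack(D, model@grid)
}

# internal: extract (dx, dy) matrices for one frame of a MotionFieldStack,
# or zeros when motion is NULL
.frameField <- function(motion, frame, grid) {
  if (is.null(motion))
    return(list(dx = matrix(0, grid@nx, grid@ny),
                dy = matrix(0, grid@nx, grid@ny)))
  list(dx = motion@D[, , 1L, frame], dy = motion@D[, , 2L, frame])
}

#' Warp an image with a displacement field
#'
#' Pull-back warp with mass conservation: samples the (prefiltered) cubic
#' B-spline interpolant of `q` at `r + D(r)` and multiplies by the Jacobian
#' determinant of the map `r -> r + D(r)` (forward finite differences).
#' Values outside the field of view are zero.
#'
#' @param q complex or real image matrix (nx x ny).
#' @param motion a [MotionFieldStack-class] (or NULL for the identity).
#' @param frame which frame of `motion` to use.
#' @return complex image matrix of the same size.
#' @export
warpImage <- function(q, motion = NULL, frame = 1L) {
  .assertFinite(q, "image")
  grid <- if (is.null(motion)) ImageGrid(nrow(q), ncol(q)) else motion@grid
  f <- .frameField(motion, frame, grid)
  storage.mode(q) <- "complex"
  cpp_warp(q, f$dx, f$dy)
}

#' Adjoint of the warp for a fixed displacement field
#'
#' Exact transpose of [warpImage()] as a linear map of the image: Jacobian
#' weighting, interpolation transpose (scatter), and the symmetric
#' spline prefilter.
#'
#' @inheritParams warpImage
#' @param g complex image matrix (nx x ny).
#' @return complex image matrix.
#' @export
warpAdjoint <- function(g, motion = NULL, frame = 1L) {
  .assertFinite(g, "image")
  grid <- if (is.null(motion)) ImageGrid(nrow(g), ncol(g)) else motion@grid
  f <- .frameField(motion, frame, grid)
  storage.mode(g) <- "complex"
  cpp_warp_adjoint(g, f$dx, f$dy)
}

#' Jacobian determinant map of a displacement field
#'
#' @param motion a [MotionFieldStack-class].
#' @param frame frame index.
#' @return real matrix of det(I + grad D) per voxel.
#' @export
jacobianDet <- function(motion, frame = 1L) {
  f <- .frameField(motion, frame, motion@grid)
  cpp_jacobian_det(f$dx, f$dy)
}

# convert containers to the argument set of the compiled model operators
.opArgs <- function(sampling, coils, motion = NULL) {
  grid <- sampling@grid
  M <- frameCount(sampling)
  if (is.null(motion)) {
    dx <- numeric(0)   # zero-motion fast path: no warp, no field arrays
    dy <- numeric(0)
  } else {
    stopifnot(dim(motion@D)[4] == M)
    dx <- array(motion@D[, , 1L, ], c(grid@nx, grid@ny, M))
    dy <- array(motion@D[, , 2L, ], c(grid@nx, grid@ny, M))
  }
  list(nx = grid@nx, ny = grid@ny, coils = coils@maps, dx = dx, dy = dy,
       samp = lapply(sampling@samp, function(v) v - 1L),
       lines = sampling@scheme == "cartesian-lines",
       warp = !is.null(motion))
}

#' Motion-conditional forward signal model
#'
#' For every frame: warp the reference image with its displacement field,
#' apply the static coil sensitivities, take the unitary 2D Fourier
#' transform, and read out the sampled k-space locations of `sampling`.
#' With zero motion this reduces to a masked coil-weighted FFT.
#'
#' @param Q complex matrix (voxels x frames) of reference images.
#' @param coils a [CoilMaps-class].
#' @param sampling a [DynamicKSpace-class] providing the sampling pattern
#'   (its stored sample values are ignored).
#' @param motion a [MotionFieldStack-class] or NULL for zero motion.
#' @return list (length frames) of complex (samples x coils) matrices.
#' @export
forwardSignal <- function(Q, coils, sampling, motion = NULL) {
  stopifnot(nrow(Q) == nVoxels(sampling@grid),
            ncol(Q) == frameCount(sampling))
  storage.mode(Q) <- "complex"
  a <- .opArgs(sampling, coils, motion)
  cpp_forward_all(Q, a$nx, a$ny, a$coils, a$dx, a$dy, a$samp, a$lines,
                  a$warp)
}

#' Adjoint of the forward signal model
#'
#' Exact adjoint of [forwardSignal()] for fixed motion: zero-filled unitary
#' inverse FFT of the samples, conjugate coil combination, and the warp
#' adjoint.
#'
#' @param data list of complex (samples x coils) matrices.
#' @inheritParams forwardSignal
#' @return complex matrix (voxels x frames).
#' @export
adjointSignal <- function(data, coils, sampling, motion = NULL) {
  stopifnot(length(data) == frameCount(sampling))
  a <- .opArgs(sampling, coils, motion)
  data <- lapply(data, function(s) { storage.mode(s) <- "complex"; s })
  cpp_adjoint_all(data, a$nx, a$ny, a$coils, a$dx, a$dy, a$samp, a$lines,
                  a$warp)
}

#' Unitary temporal Fourier transform
#'
#' DFT along the frame (column) axis of a Casorati matrix, normalized so
#' that the operator is unitary.
#'
#' @param X complex matrix (voxels x frames).
#' @return complex matrix of the same size.
#' @export
temporalFourier <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "complex"
  cpp_temporal_fft(X, FALSE)
}

#' @rdname temporalFourier
#' @export
temporalFourierAdjoint <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "complex"
  cpp_temporal_fft(X, TRUE)
}

#' Largest eigenvalue of F* F by the power method
#'
#' Power iteration on the normal operator of a linear map given as a
#' forward/adjoint closure pair. Iterates until the relative change of the
#' eigenvalue estimate drops below `tol` or `maxIter` is reached (with a
#' warning and the best estimate on non-convergence).
#'
#' @param forward,adjoint closures implementing the map and its adjoint.
#' @param xInit a starting element of the domain (used for shape; its
#'   content is replaced by a seeded random draw unless `warmStart` is
#'   given).
#' @param seed integer seed for the starting vector.
#' @param tol relative-change tolerance.
#' @param maxIter iteration cap.
#' @param warmStart optional starting vector (e.g. the iterate of a
#'   previous, nearby operator); must match `xInit` in shape.
#' @return the eigenvalue estimate, with attributes `iterations`,
#'   `converged` and `vector` (the final iterate, for warm starts).
#' @export
spectralNorm <- function(forward, adjoint, xInit, seed = 1L, tol = 1e-4,
                         maxIter = 100L, warmStart = NULL) {
  x <- if (!is.null(warmStart)) warmStart else .localSeed(seed, {
    n <- length(xInit)
    v <- complex(real = rnorm(n), imaginary = rnorm(n))
    array(v, dim = dim(xInit) %||% n)
  })
  if (!is.null(dim(xInit))) x <- matrix(x, nrow(xInit), ncol(xInit))
  gamma <- NA_real_
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    y <- adjoint(forward(x))
    nrm <- sqrt(sum(Mod(y)^2))
    if (nrm == 0) { gamma <- 0; converged <- TRUE; break }
    gammaNew <- sum(Re(Conj(x) * y)) / sum(Mod(x)^2)
    x <- y / nrm
    if (!is.na(gamma) && abs(gammaNew - gamma) <= tol * abs(gammaNew)) {
      gamma <- gammaNew
      converged <- TRUE
      break
    }
    gamma <- gammaNew
  }
  if (!converged)
    warning("power method did not converge; returning best estimate")
  structure(gamma, iterations = it, converged = converged, vector = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
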