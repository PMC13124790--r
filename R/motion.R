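# Step 2: explicit-rank B-spline motion estimation from k-space by L-BFGS.

#' Total variation of a displacement field stack
#'
#' Isotropic total variation with forward differences and zero-flux
#' boundaries, summed over frames. The default `"mixed"` variant is the 2,1
#' mixed norm over all gradient entries of both displacement components,
#' `sum_i sqrt(|grad Dx|_i^2 + |grad Dy|_i^2)`; the `"printed"` variant
#' combines the per-component isotropic sums under one root,
#' `sqrt((sum_i |grad Dx|_i)^2 + (sum_i |grad Dy|_i)^2)` per frame.
#'
#' @param motion a [MotionFieldStack-class].
#' @param variant `"mixed"` (default, used by the solver) or `"printed"`.
#' @return scalar TV value (voxel units).
#' @export
tvMotion <- function(motion, variant = c("mixed", "printed")) {
  variant <- match.arg(variant)
  dx <- array(motion@D[, , 1L, ], dim(motion@D)[c(1, 2, 4)])
  dy <- array(motion@D[, , 2L, ], dim(motion@D)[c(1, 2, 4)])
  if (variant == "mixed")
    return(cpp_tv(dx, dy, dim(dx)[1], dim(dx)[2], dim(dx)[3], FALSE)$value)
  gnorm <- function(m) {  # isotropic TV of one scalar field
    gx <- rbind(diff(m), rep(0, ncol(m)))
    gy <- t(rbind(diff(t(m)), rep(0, nrow(m))))
    sum(sqrt(gx^2 + gy^2))
  }
  total <- 0
  for (t in seq_len(dim(dx)[3]))
    total <- total + sqrt(gnorm(dx[, , t])^2 + gnorm(dy[, , t])^2)
  total
}

# pack/unpack (phi, psi) <-> flat parameter vector
.packPar <- function(phi, psi) c(as.vector(phi), as.vector(psi))
.unpackPar <- function(par, nPhi, dimPhi, dimPsi) {
  list(phi = matrix(par[seq_len(nPhi)], dimPhi[1], dimPhi[2]),
       psi = matrix(par[-seq_len(nPhi)], dimPsi[1], dimPsi[2]))
}

# evaluation core shared by motionObjective() and solveMotion(): value and
# gradient of   sum_t ||F(q_t|D_t) - s_t||^2 + lambdaTV TV(D)
# with D = (Bs phi)(Bt psi)^T, with respect to phi and psi.
.motionEval <- function(phi, psi, env, wantGrad = TRUE) {
  Bs <- env$Bs; Bt <- env$Bt
  nx <- env$nx; ny <- env$ny; M <- env$M
  ncs <- nrow(phi) / 2L
  psiD <- as.matrix(Bt %*% psi)                       # M x R
  phiX <- phi[seq_len(ncs), , drop = FALSE]
  phiY <- phi[ncs + seq_len(ncs), , drop = FALSE]
  spX <- as.matrix(Bs %*% phiX)                       # N x R
  spY <- as.matrix(Bs %*% phiY)
  dx <- array(spX %*% t(psiD), c(nx, ny, M))
  dy <- array(spY %*% t(psiD), c(nx, ny, M))
  og <- cpp_motion_obj_grad(env$Qcoef, nx, ny, env$coils, dx, dy, env$samp,
                            env$data, env$lines, wantGrad)
  tv <- if (env$lambdaTV > 0) cpp_tv(dx, dy, nx, ny, M, wantGrad)
  else list(value = 0)
  value <- og$value + env$lambdaTV * tv$value
  out <- list(value = value, dataTerm = og$value, tvTerm = tv$value)
  if (!wantGrad) return(out)
  Gx <- og$gx; Gy <- og$gy
  if (env$lambdaTV > 0) {
    Gx <- Gx + env$lambdaTV * tv$gx
    Gy <- Gy + env$lambdaTV * tv$gy
  }
  GxM <- matrix(Gx, nx * ny, M)
  GyM <- matrix(Gy, nx * ny, M)
  # chain rule through the separable expansion
  gPhiX <- as.matrix(Matrix::crossprod(Bs, GxM %*% psiD))
  gPhiY <- as.matrix(Matrix::crossprod(Bs, GyM %*% psiD))
  gPsi <- as.matrix(Matrix::crossprod(Bt,
                                      t(GxM) %*% spX + t(GyM) %*% spY))
  out$gradPhi <- rbind(gPhiX, gPhiY)
  out$gradPsi <- gPsi
  out
}

# build the fixed evaluation environment for a given Q / data / model shape
.motionEnv <- function(Q, ksp, coils, lambdaTV, ctrl, ctrlT, rank) {
  grid <- ksp@grid
  M <- frameCount(ksp)
  model0 <- LowRankMotionModel(
    phi = matrix(0, 2L * prod(rep(ctrl, length.out = 2)), rank),
    psi = matrix(0, if (is.na(ctrlT)) M else ctrlT, rank),
    ctrl = ctrl, frames = M, grid = grid, ctrlT = ctrlT)
  bases <- .motionBases(model0)
  storage.mode(Q) <- "complex"
  Qcoef <- vapply(seq_len(M), function(t)
    as.vector(cpp_prefilter(matrix(Q[, t], grid@nx, grid@ny))),
    complex(nVoxels(grid)))
  list(Bs = bases$Bs, Bt = bases$Bt, nx = grid@nx, ny = grid@ny, M = M,
       Qcoef = Qcoef, coils = coils@maps,
       samp = lapply(ksp@samp, function(v) v - 1L),
       data = ksp@samples, lines = ksp@scheme == "cartesian-lines",
       lambdaTV = lambdaTV, model0 = model0)
}

#' Motion objective value and gradient
#'
#' Evaluates `sum_t ||F(q_t | D_t) - s_t||^2 + lambdaTV TV(D)` and its exact
#' gradient with respect to the motion model coefficients, with
#' `D = (Bs phi)(Bt psi)^T`. The gradient is assembled by the chain rule
#' through sampling, FFT, coil weighting, warp (including the Jacobian
#' determinant) and the B-spline expansion.
#'
#' @param model a [LowRankMotionModel-class] carrying `phi`, `psi`.
#' @param Q complex matrix (voxels x frames) of fixed reference images.
#' @param ksp a [DynamicKSpace-class] (pattern and measured samples).
#' @param coils a [CoilMaps-class].
#' @param lambdaTV TV weight (>= 0).
#' @param wantGrad compute gradients (TRUE) or value only.
#' @return list with `value`, `dataTerm`, `tvTerm`, and (if requested)
#'   `gradPhi`, `gradPsi` matching the coefficient shapes.
#' @export
motionObjective <- function(model, Q, ksp, coils, lambdaTV = 0,
                            wantGrad = TRUE) {
  stopifnot(is(model, "LowRankMotionModel"))
  env <- .motionEnv(Q, ksp, coils, lambdaTV, model@ctrl,
                    if (model@temporalBasis == "bspline") model@ctrlT
                    else NA_integer_, model@rank)
  .motionEval(model@phi, model@psi, env, wantGrad)
}

# one L-BFGS stage on a fixed control grid; returns the best iterate and
# the objective trace
.motionStage <- function(init, env, maxit) {
  model0 <- env$model0
  dimPhi <- dim(model0@phi); dimPsi <- dim(model0@psi)
  nPhi <- prod(dimPhi)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  cache$bestVal <- Inf
  evalAt <- function(par) {
    if (!identical(par, cache$par)) {
      u <- .unpackPar(par, nPhi, dimPhi, dimPsi)
      cache$res <- .motionEval(u$phi, u$psi, env, wantGrad = TRUE)
      cache$par <- par
      cache$trace <- c(cache$trace, cache$res$value)
      if (cache$res$value < cache$bestVal) {
        cache$bestVal <- cache$res$value
        cache$bestPar <- par
      }
    }
    cache$res
  }
  fn <- function(par) evalAt(par)$value
  gr <- function(par) {
    r <- evalAt(par)
    c(as.vector(r$gradPhi), as.vector(r$gradPsi))
  }
  opt <- tryCatch(
    # pgtol = 0: the default absolute projected-gradient threshold would
    # stop prematurely on small intensity scales; rely on maxit and the
    # relative-improvement rule
    optim(.packPar(init$phi, init$psi), fn, gr, method = "L-BFGS-B",
          control = list(maxit = maxit, lmm = 10, pgtol = 0)),
    error = function(e) {
      warning("L-BFGS line search failed; returning best iterate (",
              conditionMessage(e), ")")
      NULL
    })
  par <- if (is.null(opt)) cache$bestPar else opt$par
  u <- .unpackPar(par, nPhi, dimPhi, dimPsi)
  list(phi = u$phi, psi = u$psi, trace = cache$trace,
       counts = if (!is.null(opt)) opt$counts else NA,
       convergence = if (!is.null(opt)) opt$convergence else NA_integer_)
}

#' Estimate the low-rank B-spline motion model (step 2)
#'
#' Minimizes the motion objective over `(phi, psi)` with L-BFGS (memory 10,
#' at most `maxIterMotion` iterations). Coefficients are initialized with
#' fresh uniform(-1, 1) draws, rescaled so the largest initial displacement
#' is 0.5 voxel (the raw draws are unit-free). Deterministic given the
#' seed.
#'
#' @param Q complex matrix (voxels x frames), fixed from step 1.
#' @param ksp a [DynamicKSpace-class].
#' @param coils a [CoilMaps-class].
#' @param config a [ReconConfig-class] (rank, control grids, lambdaTV,
#'   iteration cap).
#' @param seed integer seed for the random initialization (defaults to the
#'   config seed).
#' @return a [LowRankMotionModel-class] with attribute `trace` (objective
#'   values of all evaluations, convergence info).
#' @export
solveMotion <- function(Q, ksp, coils, config = ReconConfig(), seed = NULL) {
  if (is.null(seed)) seed <- config@seed
  ctrl <- c(config@ctrlX, config@ctrlY)
  envF <- .motionEnv(Q, ksp, coils, config@lambdaTV, ctrl, config@ctrlT,
                     config@rankD)
  dimPhi <- dim(envF$model0@phi)
  dimPsi <- dim(envF$model0@psi)

  init <- .localSeed(seed, {
    phi <- matrix(runif(prod(dimPhi), -1, 1), dimPhi[1], dimPhi[2])
    psi <- matrix(runif(prod(dimPsi), -1, 1), dimPsi[1], dimPsi[2])
    list(phi = phi, psi = psi)
  })
  probe <- .motionDispMax(init$phi, init$psi, envF)
  if (probe > 0) init$phi <- init$phi * (0.5 / probe)

  s2 <- .motionStage(init, envF, config@maxIterMotion)
  trace <- s2$trace

  model0 <- envF$model0
  canon <- .canonicalFactors(s2$phi, s2$psi)
  model <- LowRankMotionModel(phi = canon$phi, psi = canon$psi,
                              ctrl = model0@ctrl,
                              frames = model0@frames, grid = model0@grid,
                              ctrlT = if (model0@temporalBasis == "bspline")
                                model0@ctrlT else NA)
  final <- .motionEval(s2$phi, s2$psi, envF, wantGrad = FALSE)
  attr(model, "trace") <- list(
    evaluations = trace, value = final$value,
    dataTerm = final$dataTerm, tvTerm = final$tvTerm,
    counts = s2$counts, convergence = s2$convergence, seed = seed)
  model
}

# The factorization D = Phi Psi^T is only determined up to an invertible
# mixing of the rank components. Return the canonical principal-component
# factors: SVD of the coefficient product, orthonormal spatial factors,
# singular values absorbed into the temporal factors. Leaves the expanded
# fields unchanged.
.canonicalFactors <- function(phi, psi) {
  R <- ncol(phi)
  if (R == 1L) return(list(phi = phi, psi = psi))
  s <- svd(phi %*% t(psi), nu = R, nv = R)
  list(phi = s$u, psi = s$v %*% diag(s$d[seq_len(R)], R))
}

# largest displacement magnitude produced by (phi, psi) on the grid
.motionDispMax <- function(phi, psi, env) {
  ncs <- nrow(phi) / 2L
  psiD <- as.matrix(env$Bt %*% psi)
  mx <- 0
  for (block in list(seq_len(ncs), ncs + seq_len(ncs))) {
    sp <- as.matrix(env$Bs %*% phi[block, , drop = FALSE])
    mx <- max(mx, max(abs(sp %*% t(psiD))))
  }
  mx
}

#' Split motion components by temporal frequency
#'
#' Classifies each rank component of the motion model by the dominant
#' temporal frequency of its temporal scaling vector (the corresponding
#' column of `B_t psi`) relative to a cutoff, and reconstructs the dense
#' field stacks of the low- and high-frequency groups. Static (DC-dominant)
#' components fall in the low group; the partition is invariant to the sign
#' ambiguity of the factorization.
#'
#' @param model a [LowRankMotionModel-class].
#' @param cutoffHz frequency cutoff in Hz, inside (0, Nyquist).
#' @param frameInterval frame interval in seconds.
#' @return list with `low`, `high` (component index vectors),
#'   `dominantHz` (per component), and `lowFields`, `highFields`
#'   ([MotionFieldStack-class]; zero fields when a group is empty).
#' @export
frequencySplit <- function(model, cutoffHz, frameInterval) {
  stopifnot(is(model, "LowRankMotionModel"))
  M <- model@frames
  nyquist <- 1 / (2 * frameInterval)
  if (cutoffHz <= 0 || cutoffHz >= nyquist)
    stop("cutoff must lie inside (0, Nyquist = ", nyquist, " Hz)")
  bases <- .motionBases(model)
  psiD <- as.matrix(bases$Bt %*% model@psi)
  freqs <- (0:(M - 1)) / (M * frameInterval)
  keep <- seq_len(floor(M / 2) + 1L)     # DC .. Nyquist
  dominant <- vapply(seq_len(model@rank), function(r) {
    # the temporal mean is the static offset (removed by the mid-position
    # adjustment); classify by the oscillatory content only
    v <- psiD[, r] - mean(psiD[, r])
    if (sd(v) < 1e-12 * max(abs(psiD[, r]), 1e-300))
      return(0)                          # static component -> low group
    p <- Mod(fft(v))^2
    freqs[keep][which.max(p[keep])]
  }, numeric(1))
  low <- which(dominant < cutoffHz)
  high <- which(dominant >= cutoffHz)
  subField <- function(idx) {
    if (!length(idx)) {
      D <- array(0, c(model@grid@nx, model@grid@ny, 2L, M))
      return(MotionFieldStack(D, model@grid))
    }
    sub <- LowRankMotionModel(
      phi = model@phi[, idx, drop = FALSE],
      psi = model@psi[, idx, drop = FALSE],
      ctrl = model@ctrl, frames = M, grid = model@grid,
      ctrlT = if (model@temporalBasis == "bspline") model@ctrlT else NA)
    expandMotion(sub)
  }
  list(low = low, high = high, dominantHz = dominant,
       lowFields = subField(low), highFields = subField(high))
}
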