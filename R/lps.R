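# Step 1: motion-compensated low-rank plus sparse image reconstruction by a
# FISTA-style proximal gradient method with monotone restart.

#' Singular value thresholding
#'
#' Proximal operator of `tau * nuclear norm` on the Casorati matrix:
#' soft-thresholds the singular values by `tau`.
#'
#' @param X complex matrix.
#' @param tau threshold (>= 0).
#' @return matrix of the same size.
#' @export
svt <- function(X, tau) {
  .assertFinite(X, "matrix")
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(X)
  s <- svd(X)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0i, nrow(X), ncol(X)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * Conj(t(s$v[, keep, drop = FALSE])))
}

#' Best rank-R approximation (hard rank truncation)
#'
#' Truncated SVD of the Casorati matrix. For large matrices with small R a
#' warm-startable subspace iteration is used; otherwise a dense SVD.
#'
#' @param X complex matrix (voxels x frames).
#' @param R target rank (1 <= R <= min(dim)).
#' @param vInit optional (frames x R) right-subspace warm start.
#' @return the truncation, with attribute `v` (right subspace) for warm
#'   starts.
#' @export
hardRankTruncate <- function(X, R, vInit = NULL) {
  .assertFinite(X, "matrix")
  R <- as.integer(R)
  if (R < 1L) stop("rank must be >= 1")
  if (R > min(dim(X))) stop("rank exceeds matrix dimensions")
  if (min(dim(X)) <= 64L || R >= min(dim(X)) / 2L) {
    s <- svd(X, nu = R, nv = R)
    Xr <- s$u %*% (s$d[seq_len(R)] * Conj(t(s$v)))
    return(structure(Xr, v = s$v))
  }
  M <- ncol(X)
  V <- if (!is.null(vInit) && identical(dim(vInit), c(M, R))) vInit
  else diag(1 + 0i, M)[, seq_len(R), drop = FALSE]
  sv <- rep(Inf, R)
  for (it in seq_len(100L)) {
    W <- X %*% V                       # N x R
    W <- qr.Q(qr(W))
    V <- Conj(t(Conj(t(W)) %*% X))     # M x R  (X^H W)
    svNew <- sqrt(colSums(Mod(V)^2))
    V <- qr.Q(qr(V))
    if (max(abs(svNew - sv)) <= 1e-9 * max(svNew, 1e-300)) { sv <- svNew; break }
    sv <- svNew
  }
  B <- X %*% V
  Xr <- B %*% Conj(t(V))
  structure(Xr, v = V)
}

#' Proximal operator of the temporal-Fourier L1 penalty
#'
#' `prox` of `tau * ||T S||_1` with the unitary temporal Fourier transform
#' `T`: transforms along frames, applies the phase-preserving complex soft
#' threshold `x -> x max(1 - tau/|x|, 0)`, and transforms back.
#'
#' @param S complex matrix (voxels x frames).
#' @param tau threshold (>= 0).
#' @return matrix of the same size.
#' @export
proxSparseTF <- function(S, tau) {
  .assertFinite(S, "matrix")
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(S)
  Z <- temporalFourier(S)
  m <- Mod(Z)
  shrink <- pmax(1 - tau / pmax(m, .Machine$double.xmin), 0)
  out <- temporalFourierAdjoint(Z * shrink)
  # ||T S'||_1 falls out of the shrinkage for free
  attr(out, "l1") <- sum(pmax(m - tau, 0))
  out
}

# objective of the image problem at fixed motion:
#   sum_t ||F(q_t|D_t) - s_t||^2 + lambdaS ||T S||_1 (+ lambdaL ||L||_*)
.lpsObjective <- function(L, S, coils, ksp, motion, config,
                          dataTerm = NULL, l1S = NULL) {
  if (is.null(dataTerm)) {
    a <- .opArgs(ksp, coils, motion)
    Q <- L + S
    storage.mode(Q) <- "complex"
    r <- cpp_lps_resid_grad(Q, a$nx, a$ny, a$coils, a$dx, a$dy, a$samp,
                            ksp@samples, a$lines, a$warp, FALSE)
    dataTerm <- r$value
  }
  if (is.null(l1S)) l1S <- sum(Mod(temporalFourier(S)))
  reg <- config@lambdaS * l1S
  if (is.na(config@rankL)) reg <- reg + config@lambdaL * sum(svd(L)$d)
  list(value = dataTerm + reg, dataTerm = dataTerm, regTerm = reg)
}

#' Objective value of the image reconstruction problem
#'
#' Evaluates the data-consistency term plus the configured regularization at
#' a given (L, S) pair and fixed motion. Mainly for monitoring and testing.
#'
#' @param ref a [ReferenceSeries-class].
#' @param coils a [CoilMaps-class].
#' @param ksp a [DynamicKSpace-class].
#' @param motion a [MotionFieldStack-class] or NULL.
#' @param config a [ReconConfig-class].
#' @return list with `value`, `dataTerm`, `regTerm`.
#' @export
lpsObjective <- function(ref, coils, ksp, motion = NULL,
                         config = ReconConfig()) {
  .lpsObjective(ref@L, ref@S, coils, ksp, motion, config)
}

#' Motion-compensated L+S reconstruction (step 1)
#'
#' Solves for the contrast-varying reference series `Q = L + S` at fixed
#' motion by a FISTA-style proximal gradient method with monotone restart:
#' a gradient step on the data term through the motion-conditional forward
#' model, then a rank prox on L (hard rank truncation when an explicit rank
#' is configured, singular value thresholding otherwise) and the
#' temporal-Fourier soft threshold on S, applied sequentially. The step size
#' is `stepFactor / gamma` with `gamma` from [spectralNorm()] of the current
#' operator; thresholds are scaled by the step size. Stops when the
#' normalized objective change stays below `tol` for `tolIters` consecutive
#' iterations, or at the iteration cap.
#'
#' @param ksp a [DynamicKSpace-class].
#' @param coils a [CoilMaps-class].
#' @param motion a [MotionFieldStack-class] (NULL = zero motion, i.e. the
#'   plain non-motion-corrected L+S baseline).
#' @param config a [ReconConfig-class].
#' @param init optional [ReferenceSeries-class] warm start.
#' @param gamma optional precomputed largest eigenvalue of F F*.
#' @param powerWarm optional warm-start vector for the power method (the
#'   `vector` attribute of a previous estimate).
#' @return a [ReferenceSeries-class] with attribute `trace` (list with the
#'   objective/data-term traces, `gamma`, `powerVector` and `iterations`).
#' @export
solveLps <- function(ksp, coils, motion = NULL, config = ReconConfig(),
                     init = NULL, gamma = NULL, powerWarm = NULL) {
  a <- .opArgs(ksp, coils, motion)
  N <- nVoxels(ksp@grid); M <- frameCount(ksp)

  if (is.null(gamma)) {
    fwd <- function(X) cpp_forward_all(X, a$nx, a$ny, a$coils, a$dx, a$dy,
                                       a$samp, a$lines, a$warp)
    adj <- function(d) cpp_adjoint_all(d, a$nx, a$ny, a$coils, a$dx, a$dy,
                                       a$samp, a$lines, a$warp)
    gamma <- spectralNorm(fwd, adj, matrix(0i, N, M), seed = config@seed,
                          tol = config@powerTol,
                          maxIter = config@powerMaxIter,
                          warmStart = powerWarm)
  }
  if (gamma <= 0) stop("spectral norm estimate must be > 0")
  eta <- config@stepFactor / as.numeric(gamma)

  if (is.null(init)) {
    L <- matrix(0i, N, M); S <- matrix(0i, N, M)
  } else {
    L <- init@L; S <- init@S
  }
  Ly <- L; Sy <- S
  tmom <- 1
  vWarm <- NULL
  objTrace <- numeric(0)
  dataTrace <- numeric(0)
  streak <- 0L
  lastObj <- Inf
  iters <- 0L

  for (it in seq_len(config@maxIterLps)) {
    iters <- it
    Qy <- Ly + Sy
    storage.mode(Qy) <- "complex"
    rg <- cpp_lps_resid_grad(Qy, a$nx, a$ny, a$coils, a$dx, a$dy, a$samp,
                             ksp@samples, a$lines, a$warp, TRUE)
    if (it > 1 && rg$value > 1e3 * max(dataTrace[1], .Machine$double.xmin))
      stop("image reconstruction diverged (data term grew by > 1e3)")
    Mnew <- Qy - eta * rg$grad
    Lnew <- if (!is.na(config@rankL)) {
      tr <- hardRankTruncate(Mnew - Sy, config@rankL, vInit = vWarm)
      vWarm <- attr(tr, "v")
      tr
    } else svt(Mnew - Sy, eta * config@lambdaL)
    Snew <- proxSparseTF(Mnew - Lnew, eta * config@lambdaS)
    l1S <- attr(Snew, "l1")
    attr(Snew, "l1") <- NULL

    # exact objective at the new iterate (value-only forward pass) governs
    # the monotone restart and the stopping rule
    Qn <- Lnew + Snew
    storage.mode(Qn) <- "complex"
    dataNew <- cpp_lps_resid_grad(Qn, a$nx, a$ny, a$coils, a$dx, a$dy,
                                  a$samp, ksp@samples, a$lines, a$warp,
                                  FALSE)$value
    obj <- .lpsObjective(Lnew, Snew, coils, ksp, motion, config,
                         dataTerm = dataNew, l1S = l1S)$value
    objTrace <- c(objTrace, obj)
    dataTrace <- c(dataTrace, dataNew)

    if (obj > lastObj) {        # monotone restart: drop momentum
      Ly <- Lnew; Sy <- Snew
      tmom <- 1
    } else {
      tNew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
      beta <- (tmom - 1) / tNew
      Ly <- Lnew + beta * (Lnew - L)
      Sy <- Snew + beta * (Snew - S)
      tmom <- tNew
    }
    relChange <- abs(obj - lastObj) / max(abs(obj), .Machine$double.xmin)
    streak <- if (is.finite(lastObj) && relChange < config@tol)
      streak + 1L else 0L
    L <- Lnew; S <- Snew
    lastObj <- obj
    if (streak >= config@tolIters) break
  }

  ref <- ReferenceSeries(L, S, ksp@grid)
  attr(ref, "trace") <- list(objective = objTrace, dataTerm = dataTrace,
                             gamma = as.numeric(gamma), iterations = iters,
                             powerVector = attr(gamma, "vector"))
  ref
}
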