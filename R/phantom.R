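# Analytic short-axis first-pass perfusion phantom.
#
# Geometry (in fractions of the matrix size, 0-based voxel coordinates):
# an elliptical body, a myocardial annulus with an interior LV blood disc,
# and an RV blood crescent. Cardiac motion is a smooth radial contraction
# about the heart center, defined directly as the backward (pull-back) map
#   r0 = c + (1 + alpha_t * exp(-(s/sigma_h)^2)) (r - c),   s = |r - c|,
# so the exact displacement D_t(r) = r0 - r is rank-1 separable in space and
# time and maps every frame onto the rest (frame-0 phase) geometry.
# Respiration and bulk motion are translations applied the same way.

.phantomGeometry <- function(nx, ny) {
  list(cb = c((nx - 1) / 2, (ny - 1) / 2),          # body center
       ax = 0.40 * nx, ay = 0.34 * ny,              # body semi-axes
       ch = c(0.45 * (nx - 1), 0.42 * (ny - 1)),    # heart center
       rEndo = 0.09 * nx, rEpi = 0.15 * nx,         # LV radii
       cRvOff = -0.18 * nx, rRv = 0.12 * nx,        # RV disc
       rRvExcl = 0.17 * nx,                         # RV exclusion radius
       sigmaH = 0.18 * nx)                          # motion decay length
}

# label codes
.LBL <- c(background = 0L, body = 1L, myo = 2L, lv = 3L, rv = 4L)

# labels evaluated at rest-geometry coordinates (vectors x0, y0)
.labelsAt <- function(x0, y0, geo) {
  sh <- sqrt((x0 - geo$ch[1])^2 + (y0 - geo$ch[2])^2)
  sr <- sqrt((x0 - (geo$ch[1] + geo$cRvOff))^2 + (y0 - geo$ch[2])^2)
  inBody <- ((x0 - geo$cb[1]) / geo$ax)^2 + ((y0 - geo$cb[2]) / geo$ay)^2 <= 1
  lab <- ifelse(inBody, .LBL["body"], .LBL["background"])
  lab[inBody & sr <= geo$rRv & sh > geo$rRvExcl] <- .LBL["rv"]
  lab[inBody & sh <= geo$rEpi & sh > geo$rEndo] <- .LBL["myo"]
  lab[inBody & sh <= geo$rEndo] <- .LBL["lv"]
  as.integer(lab)
}

# temporal motion amplitudes; t0 in seconds (frame start times)
.cardiacAmplitude <- function(t0, config) {
  phase <- (t0 %% config@heartPeriod) / config@heartPeriod
  config@cardiacContraction * sin(pi * phase)^4
}

.respShift <- function(t0, config) {
  config@respAmplitude * sin(2 * pi * t0 / config@respPeriod)
}

#' Saturation-recovery signal intensity
#'
#' Ideal saturation-recovery signal
#' `s = M0 sin(flip) (1 - exp(-Tsat / T1))`: monotone increasing in the
#' saturation delay and decreasing in T1. `Tsat` and `T1` only enter through
#' their ratio, so any common time unit may be used.
#'
#' @param M0 equilibrium magnetization.
#' @param T1 longitudinal relaxation time (> 0).
#' @param Tsat saturation delay (> 0), same unit as `T1`.
#' @param flip flip angle in degrees.
#' @return signal intensity (same unit as `M0`).
#' @export
saturationRecoverySignal <- function(M0, T1, Tsat, flip) {
  if (any(T1 <= 0)) stop("T1 must be > 0")
  if (any(Tsat <= 0)) stop("Tsat must be > 0")
  M0 * sin(flip * pi / 180) * (1 - exp(-Tsat / T1))
}

#' Gamma-variate bolus concentration
#'
#' First-pass contrast kinetics per compartment: a gamma-variate
#' `c(t) = A ((t-t0)/(alpha beta))^alpha exp(alpha - (t-t0)/beta)` for
#' `t > t0` (0 before), normalized so the peak value is `A` at
#' `t = t0 + alpha beta`. Compartment onsets follow the first-pass order
#' RV, then LV, then myocardium.
#'
#' @param t time in seconds (vector allowed).
#' @param compartment `"rv"`, `"lv"` or `"myo"`.
#' @param config a [PhantomConfig-class].
#' @return concentration in mmol/L.
#' @export
bolusConcentration <- function(t, compartment = c("rv", "lv", "myo"),
                               config = PhantomConfig()) {
  compartment <- match.arg(compartment)
  if (config@bolusShape <= 0 || config@bolusScale <= 0)
    stop("gamma-variate shape and scale must be > 0")
  onset <- switch(compartment, rv = config@rvOnset, lv = config@lvOnset,
                  myo = config@myoOnset)
  A <- config@peakConc[[compartment]]
  a <- config@bolusShape; b <- config@bolusScale
  tau <- pmax(t - onset, 0)
  ifelse(tau > 0, A * (tau / (a * b))^a * exp(a - tau / b), 0)
}

# per-compartment T1 at time t (seconds): 1/T1(t) = 1/T10 + r1 c(t)
.t1At <- function(t, config) {
  cbind(lv   = 1 / (1 / config@t1Blood +
                      config@r1 * bolusConcentration(t, "lv", config)),
        rv   = 1 / (1 / config@t1Blood +
                      config@r1 * bolusConcentration(t, "rv", config)),
        myo  = 1 / (1 / config@t1Myo +
                      config@r1 * bolusConcentration(t, "myo", config)),
        body = rep(config@t1Body, length(t)))
}

# separable Gaussian smoothing with reflected boundary
.gaussSmooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  sm1 <- function(m) {  # smooth along rows (first dim), reflect
    n <- nrow(m)
    out <- m * k[r + 1]
    for (o in 1:r) {  # 'reflect' boundary: (c b a | a b c)
      idxu <- seq_len(n) + o; idxu[idxu > n] <- 2 * n + 1 - idxu[idxu > n]
      idxd <- seq_len(n) - o; idxd[idxd < 1] <- 1 - idxd[idxd < 1]
      out <- out + k[r + 1 + o] * m[idxu, , drop = FALSE] +
        k[r + 1 - o] * m[idxd, , drop = FALSE]
    }
    out
  }
  t(sm1(t(sm1(img))))
}

#' Generate the analytic perfusion phantom
#'
#' Builds the moving, contrast-enhancing phantom: noiseless frames, the
#' motion-static reference frames (contrast on, motion off), exact pull-back
#' motion fields, per-frame segmentation label maps and the compartment
#' enhancement curves. Deterministic given the configuration.
#'
#' @param config a [PhantomConfig-class].
#' @return a [PhantomTruth-class].
#' @export
generatePhantom <- function(config = PhantomConfig()) {
  validObject(config)
  nx <- config@nx; ny <- config@ny; M <- config@frames
  geo <- .phantomGeometry(nx, ny)
  grid <- ImageGrid(nx, ny)
  t0 <- (seq_len(M) - 1) * config@dt
  alpha <- .cardiacAmplitude(t0, config)
  shiftY <- .respShift(t0, config)
  shiftX <- rep(0, M)
  bulk <- t0 >= config@bulkOnset
  shiftX <- shiftX + config@bulkShift[1] * bulk
  shiftY <- shiftY + config@bulkShift[2] * bulk

  # field-of-view containment: translated body plus a safety margin
  maxSh <- max(abs(c(shiftX, shiftY)))
  if (geo$cb[1] - geo$ax - maxSh < 1 || geo$cb[1] + geo$ax + maxSh > nx - 2 ||
      geo$cb[2] - geo$ay - maxSh < 1 || geo$cb[2] + geo$ay + maxSh > ny - 2)
    stop("motion amplitude too large: anatomy exits the field of view")

  xs <- rep(0:(nx - 1), times = ny)
  ys <- rep(0:(ny - 1), each = nx)

  curves <- cbind(rv = bolusConcentration(t0, "rv", config),
                  lv = bolusConcentration(t0, "lv", config),
                  myo = bolusConcentration(t0, "myo", config))
  T1 <- .t1At(t0, config)
  sr <- function(M0, T1v)
    saturationRecoverySignal(M0, T1v, config@Tsat, config@flip)
  # per-frame compartment intensities
  inten <- cbind(background = rep(0, M),
                 body = sr(config@m0[["body"]], T1[, "body"]),
                 myo = sr(config@m0[["myo"]], T1[, "myo"]),
                 lv = sr(config@m0[["blood"]], T1[, "lv"]),
                 rv = sr(config@m0[["blood"]], T1[, "rv"]))

  frames <- matrix(0, nx * ny, M)
  refFrames <- matrix(0, nx * ny, M)
  labels <- array(0L, c(nx, ny, M))
  D <- array(0, c(nx, ny, 2L, M))
  lab0 <- .labelsAt(xs, ys, geo)  # rest geometry labels

  for (t in seq_len(M)) {
    xp <- xs - shiftX[t]; yp <- ys - shiftY[t]
    s <- sqrt((xp - geo$ch[1])^2 + (yp - geo$ch[2])^2)
    ex <- exp(-(s / geo$sigmaH)^2)
    g <- 1 + alpha[t] * ex
    x0 <- geo$ch[1] + g * (xp - geo$ch[1])
    y0 <- geo$ch[2] + g * (yp - geo$ch[2])
    D[, , 1L, t] <- x0 - xs
    D[, , 2L, t] <- y0 - ys
    labt <- .labelsAt(x0, y0, geo)
    labels[, , t] <- labt
    # in-plane magnetization is conserved under the deformation, so frame
    # intensities carry the analytic Jacobian determinant of the backward
    # radial map r -> c + g(s) (r - c):  det = g(s) (g(s) + s g'(s))
    gp <- alpha[t] * ex * (-2 * s / geo$sigmaH^2)
    detA <- g * (g + s * gp)
    img <- inten[t, labt + 1L] * detA
    frames[, t] <- as.vector(.gaussSmooth(matrix(img, nx, ny), 0.7))
    img0 <- inten[t, lab0 + 1L]
    refFrames[, t] <- as.vector(.gaussSmooth(matrix(img0, nx, ny), 0.7))
  }

  new("PhantomTruth", frames = frames, refFrames = refFrames,
      motion = MotionFieldStack(D, grid), labels = labels, curves = curves,
      config = config)
}

#' Analytic coil sensitivity maps
#'
#' Smooth complex Gaussian-lobe sensitivities centered on a ring around the
#' field of view with a mild coil-specific linear phase, normalized so the
#' maximum root-sum-of-squares is 1. Deterministic given grid and count.
#'
#' @param grid an [ImageGrid-class].
#' @param nCoils number of coils (>= 1). `nCoils = 1` gives a single
#'   uniform coil (plain Fourier sampling).
#' @return a [CoilMaps-class].
#' @export
makeCoilMaps <- function(grid, nCoils) {
  nCoils <- as.integer(nCoils)
  if (nCoils < 1L) stop("coil count must be >= 1")
  nx <- grid@nx; ny <- grid@ny
  if (nCoils == 1L)
    return(CoilMaps(array(1 + 0i, c(nx, ny, 1L)), grid))
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  xs <- matrix(rep(0:(nx - 1), ny), nx, ny)
  ys <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  maps <- array(0i, c(nx, ny, nCoils))
  rad <- 0.55 * max(nx, ny)
  width <- 0.45 * max(nx, ny)
  for (c in seq_len(nCoils)) {
    th <- 2 * pi * (c - 1) / nCoils
    px <- cx + rad * cos(th); py <- cy + rad * sin(th)
    mag <- exp(-((xs - px)^2 + (ys - py)^2) / (2 * width^2))
    ph <- 0.2 * pi * ((xs - cx) * cos(th) + (ys - cy) * sin(th)) / max(nx, ny)
    maps[, , c] <- mag * exp(1i * ph)
  }
  rss <- sqrt(apply(Mod(maps)^2, c(1, 2), sum))
  CoilMaps(maps / max(rss), grid)
}

#' Per-frame sampling pattern
#'
#' Cartesian pseudo-random sampling draws `readouts` full ky lines per
#' frame: a fixed low-frequency core of `centerLines` lines around DC plus
#' a pseudo-random remainder re-drawn per frame from a seeded RNG. Radial
#' golden-angle sampling continues spoke angles across frames in increments
#' of 111.246 degrees and grids each spoke to the nearest Cartesian k-space
#' locations.
#'
#' @param scheme `"cartesian_pseudorandom"` or `"radial_golden_angle"`.
#' @param frame frame index (1-based).
#' @param readouts lines (Cartesian) or spokes (radial) per frame.
#' @param grid an [ImageGrid-class].
#' @param seed integer seed (per-frame draws are derived from it).
#' @param centerLines fully sampled central lines (Cartesian only).
#' @return integer vector: sorted ky line indices (1-based bins) for
#'   Cartesian, or unique 1-based linear k-grid indices for radial.
#' @export
makeSampling <- function(scheme = c("cartesian_pseudorandom",
                                    "radial_golden_angle"),
                         frame, readouts, grid, seed = 1L,
                         centerLines = 4L) {
  scheme <- match.arg(scheme)
  nx <- grid@nx; ny <- grid@ny
  readouts <- as.integer(readouts)
  if (readouts < 1L) stop("readouts must be >= 1")
  if (scheme == "cartesian_pseudorandom") {
    if (readouts > ny) stop("more readouts than k-space lines")
    # 0-based ky bins closest to DC: 0, 1, ny-1, 2, ny-2, ...
    ord <- c(0L, as.vector(rbind(seq_len(ny %/% 2), ny - seq_len(ny %/% 2))))
    ord <- unique(ord[ord >= 0 & ord < ny])
    core <- ord[seq_len(min(centerLines, readouts))]
    rest <- setdiff(0:(ny - 1L), core)
    nRand <- readouts - length(core)
    lines <- if (nRand > 0)
      c(core, .localSeed(seed + 7919L * frame, sample(rest, nRand)))
    else core
    sort(as.integer(lines + 1L))
  } else {
    golden <- 111.246 * pi / 180
    spoke0 <- (frame - 1L) * readouts
    rho <- seq(-floor(nx / 2), ceiling(nx / 2) - 1L)
    idx <- integer(0)
    for (j in seq_len(readouts)) {
      th <- ((spoke0 + j - 1L) * golden) %% pi
      kx <- round(rho * cos(th)); ky <- round(rho * sin(th))
      kx <- pmin(pmax(kx, -floor(nx / 2)), ceiling(nx / 2) - 1L)
      ky <- pmin(pmax(ky, -floor(ny / 2)), ceiling(ny / 2) - 1L)
      bx <- (kx + nx) %% nx; by <- (ky + ny) %% ny
      idx <- c(idx, bx + nx * by + 1L)
    }
    sort(unique(as.integer(idx)))
  }
}

# sampling pattern for every frame of a phantom configuration
.samplingAll <- function(config, grid) {
  scheme <- if (config@scheme == "cartesian_pseudorandom")
    "cartesian-lines" else "gridded-points"
  samp <- lapply(seq_len(config@frames), function(t)
    makeSampling(config@scheme, t, config@readouts, grid, config@seed,
                 config@centerLines))
  list(scheme = scheme, samp = samp)
}

#' Fully sampled Cartesian pattern
#'
#' @param grid an [ImageGrid-class].
#' @param frames frame count.
#' @return a sampling list usable with [simulateKspace()].
#' @export
fullSampling <- function(grid, frames) {
  list(scheme = "cartesian-lines",
       samp = replicate(frames, seq_len(grid@ny), simplify = FALSE))
}

#' Simulate undersampled multi-coil k-space from phantom truth
#'
#' Applies the coil sensitivities to each noiseless frame, takes the unitary
#' FFT, reads out the sampled k-space locations, and adds complex Gaussian
#' noise of standard deviation `sigma` per sample. Deterministic given the
#' seed.
#'
#' @param truth a [PhantomTruth-class].
#' @param coils a [CoilMaps-class].
#' @param sampling a list with elements `scheme` and `samp` (see
#'   [fullSampling()]), or NULL to use the pattern from `truth@config`.
#' @param sigma complex noise SD per k-space sample; NA uses the phantom
#'   configuration (about 30 dB SNR on the time-averaged image by default).
#' @param seed integer noise seed; NA uses `truth@config@seed`.
#' @return a [DynamicKSpace-class].
#' @export
simulateKspace <- function(truth, coils, sampling = NULL, sigma = NA,
                           seed = NA) {
  grid <- truth@motion@grid
  M <- frameCount(truth)
  if (is.null(sampling)) sampling <- .samplingAll(truth@config, grid)
  if (is.na(seed)) seed <- truth@config@seed
  if (is.na(sigma)) sigma <- truth@config@noiseSigma
  if (is.na(sigma)) {
    avg <- rowMeans(truth@frames)
    body <- avg > 0.05 * max(avg)
    sigma <- mean(avg[body]) / 10^(30 / 20)   # ~30 dB SNR in image domain
  }
  if (sigma < 0) stop("noise sigma must be >= 0")
  Q <- truth@frames
  storage.mode(Q) <- "complex"
  lines <- sampling$scheme == "cartesian-lines"
  samp0 <- lapply(sampling$samp, function(v) as.integer(v) - 1L)
  raw <- cpp_forward_all(Q, grid@nx, grid@ny, coils@maps, numeric(0),
                         numeric(0), samp0, lines, FALSE)
  if (sigma > 0) {
    raw <- .localSeed(seed + 101L, lapply(raw, function(s) {
      n <- length(s)
      s + complex(real = rnorm(n, 0, sigma / sqrt(2)),
                  imaginary = rnorm(n, 0, sigma / sqrt(2)))
    }))
  }
  DynamicKSpace(grid, sampling$samp, raw,
                scheme = if (lines) "cartesian-lines" else "gridded-points")
}

#' One-call phantom dataset
#'
#' Convenience wrapper: generate the phantom, build coil maps, and simulate
#' the undersampled k-space of the configured acquisition.
#'
#' @param config a [PhantomConfig-class].
#' @return list with elements `kspace` ([DynamicKSpace-class]), `coils`
#'   ([CoilMaps-class]) and `truth` ([PhantomTruth-class]).
#' @export
simulatePerfusionDataset <- function(config = PhantomConfig()) {
  truth <- generatePhantom(config)
  coils <- makeCoilMaps(truth@motion@grid, config@nCoils)
  kspace <- simulateKspace(truth, coils)
  list(kspace = kspace, coils = coils, truth = truth)
}
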