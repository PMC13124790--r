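# linear/nonlinear building blocks: B-spline motion expansion, warping with
# Jacobian determinant, forward/adjoint signal model, temporal Fourier,
# spectral norm

test_that("motion expansion matches brute-force tensor-product evaluation", {
  set.seed(10)
  nx <- 16; ny <- 16; M <- 8; ncx <- 6; ncy <- 5; R <- 2
  grid <- ImageGrid(nx, ny)
  phi <- matrix(rnorm(2 * ncx * ncy * R), 2 * ncx * ncy, R)
  psi <- matrix(rnorm(M * R), M, R)
  model <- LowRankMotionModel(phi, psi, ctrl = c(ncx, ncy), frames = M,
                              grid = grid)
  D <- expandMotion(model)@D

  # independent dense evaluation: cubic FFD basis weights by direct loops
  b3 <- function(tt, k) switch(k,
    (1 - tt)^3 / 6, (3 * tt^3 - 6 * tt^2 + 4) / 6,
    (-3 * tt^3 + 3 * tt^2 + 3 * tt + 1) / 6, tt^3 / 6)
  basis1d <- function(n, nc) {
    h <- (n - 1) / (nc - 3)
    B <- matrix(0, n, nc)
    for (p in 0:(n - 1)) {
      u <- p / h; i0 <- min(floor(u), nc - 4); tt <- u - i0
      for (k in 1:4) B[p + 1, i0 + k] <- b3(tt, k)
    }
    B
  }
  Bx <- basis1d(nx, ncx); By <- basis1d(ny, ncy)
  Dref <- array(0, c(nx, ny, 2, M))
  for (r in seq_len(R)) {
    cx <- array(phi[seq_len(ncx * ncy), r], c(ncx, ncy))
    cy <- array(phi[ncx * ncy + seq_len(ncx * ncy), r], c(ncx, ncy))
    sx <- Bx %*% cx %*% t(By)
    sy <- Bx %*% cy %*% t(By)
    for (t in seq_len(M)) {
      Dref[, , 1, t] <- Dref[, , 1, t] + sx * psi[t, r]
      Dref[, , 2, t] <- Dref[, , 2, t] + sy * psi[t, r]
    }
  }
  expect_lt(max(abs(D - Dref)), 1e-10)

  # zero coefficients -> zero fields; constant translation replicates
  model0 <- LowRankMotionModel(phi * 0, psi, ctrl = c(ncx, ncy),
                               frames = M, grid = grid)
  expect_equal(max(abs(expandMotion(model0)@D)), 0)
  phiT <- rbind(matrix(2, ncx * ncy, 1), matrix(-1, ncx * ncy, 1))
  modelT <- LowRankMotionModel(phiT, matrix(1, M, 1), ctrl = c(ncx, ncy),
                               frames = M, grid = grid)
  DT <- expandMotion(modelT)@D
  expect_equal(max(abs(DT[, , 1, ] - 2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(DT[, , 2, ] + 1)), 0, tolerance = 1e-12)

  # linearity in phi and psi separately
  m2 <- LowRankMotionModel(2 * phi, psi, ctrl = c(ncx, ncy), frames = M,
                           grid = grid)
  expect_equal(expandMotion(m2)@D, 2 * D, tolerance = 1e-12)
  m3 <- LowRankMotionModel(phi, 3 * psi, ctrl = c(ncx, ncy), frames = M,
                           grid = grid)
  expect_equal(expandMotion(m3)@D, 3 * D, tolerance = 1e-12)

  expect_error(LowRankMotionModel(phi, psi, ctrl = c(32, 5), frames = M,
                                  grid = grid), "exceeds")
})

test_that("warp is exact for identity and translations and conserves mass", {
  set.seed(11)
  nx <- 24; ny <- 24
  grid <- ImageGrid(nx, ny)
  q <- matrix(rcplx(nx * ny), nx, ny)
  expect_lt(max(Mod(warpImage(q) - q)), 1e-12)

  # integer translation: exact shift, unit determinant
  qs <- matrix(0, nx, ny); qs[8:14, 8:14] <- 1
  Dtr <- array(0, c(nx, ny, 2, 1)); Dtr[, , 1, 1] <- 2
  mtr <- MotionFieldStack(Dtr, grid)
  ht <- Re(warpImage(qs, mtr, 1))
  expect_equal(ht[6:12, 8:14], qs[8:14, 8:14], tolerance = 1e-12)
  expect_equal(jacobianDet(mtr, 1), matrix(1, nx, ny))

  # uniform dilation D = 0.1 r: interior determinant is 1.1^2 exactly
  # (the map is linear so forward differences are exact) and the integral
  # of an interior blob is conserved by the determinant weighting
  xs <- matrix(rep(0:(nx - 1), ny), nx, ny)
  ys <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  Dd <- array(0, c(nx, ny, 2, 1))
  Dd[, , 1, 1] <- 0.1 * xs; Dd[, , 2, 1] <- 0.1 * ys
  md <- MotionFieldStack(Dd, grid)
  det <- jacobianDet(md, 1)
  expect_equal(det[1:(nx - 1), 1:(ny - 1)],
               matrix(1.21, nx - 1, ny - 1), tolerance = 1e-12)
  blob <- exp(-((xs - 8)^2 + (ys - 8)^2) / 4)
  expect_equal(sum(Re(warpImage(blob, md, 1))) / sum(blob), 1,
               tolerance = 0.01)
})

test_that("forward model reduces to a masked FFT and obeys the shift theorem", {
  nx <- 32; ny <- 32
  grid <- ImageGrid(nx, ny)
  c1 <- makeCoilMaps(grid, 1)
  fs <- fullSampling(grid, 1)
  ksp <- DynamicKSpace(grid, fs$samp, list(matrix(0i, nx * ny, 1)))
  xs <- matrix(rep(0:(nx - 1), ny), nx, ny)
  ys <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  blob <- exp(-((xs - 15)^2 + (ys - 15)^2) / 18)

  # D = 0, uniform coil: equals the unitary FFT at the sampled locations
  F0 <- forwardSignal(matrix(blob, ncol = 1), c1, ksp)[[1]]
  expect_lt(max(Mod(F0 - as.vector(fft(blob)) / sqrt(nx * ny))), 1e-10)

  # global non-integer translation multiplies by a linear phase
  tau <- c(2.3, -1.7)
  Dt <- array(0, c(nx, ny, 2, 1))
  Dt[, , 1, 1] <- tau[1]; Dt[, , 2, 1] <- tau[2]
  Fm <- forwardSignal(matrix(blob, ncol = 1), c1, ksp,
                      MotionFieldStack(Dt, grid))[[1]]
  kc <- kSpaceCoordinates(ksp, 1)
  phase <- exp(1i * 2 * pi * (kc[, 1] * tau[1] / nx + kc[, 2] * tau[2] / ny))
  expect_lt(sqrt(sum(Mod(Fm - F0 * phase)^2) / sum(Mod(F0)^2)), 1e-3)
})

test_that("every forward/adjoint pair passes randomized dot-product tests", {
  set.seed(12)
  nx <- 16; ny <- 16; M <- 5; C <- 2
  grid <- ImageGrid(nx, ny)
  coils <- makeCoilMaps(grid, C)
  for (scheme in c("lines", "points")) {
    ksp <- if (scheme == "lines") tinyKspace(nx, ny, M, C, 5, seed = 13)
    else {
      samp <- lapply(seq_len(M), function(t) sort(sample(nx * ny, 60)))
      DynamicKSpace(grid, samp,
                    lapply(seq_len(M), function(t) matrix(0i, 60, C)),
                    scheme = "gridded-points")
    }
    for (useMotion in c(FALSE, TRUE)) {
      mot <- if (useMotion) tinyMotion(nx, ny, M, seed = 14) else NULL
      errs <- replicate(20, {
        X <- matrix(rcplx(nx * ny * M), nx * ny, M)
        Y <- lapply(seq_len(M), function(t)
          matrix(rcplx(nrow(ksp@samples[[t]]) * C),
                 nrow(ksp@samples[[t]]), C))
        FX <- forwardSignal(X, coils, ksp, mot)
        AY <- adjointSignal(Y, coils, ksp, mot)
        lhs <- sum(vapply(seq_len(M), function(t)
          sum(Conj(FX[[t]]) * Y[[t]]), complex(1)))
        rhs <- sum(Conj(X) * AY)
        Mod(lhs - rhs) / sqrt(sum(Mod(X)^2) *
                                sum(vapply(Y, function(y) sum(Mod(y)^2),
                                           numeric(1))))
      })
      expect_lt(max(errs), 1e-6)
    }
  }
  # warp/warp-adjoint pair on its own
  mot <- tinyMotion(nx, ny, 1, seed = 15)
  errs <- replicate(20, {
    x <- matrix(rcplx(nx * ny), nx, ny)
    y <- matrix(rcplx(nx * ny), nx, ny)
    lhs <- sum(Conj(warpImage(x, mot, 1)) * y)
    rhs <- sum(Conj(x) * warpAdjoint(y, mot, 1))
    Mod(lhs - rhs) / sqrt(sum(Mod(x)^2) * sum(Mod(y)^2))
  })
  expect_lt(max(errs), 1e-6)
})

test_that("adjoint is linear and reduces to the inverse FFT when trivial", {
  nx <- 16; ny <- 16
  grid <- ImageGrid(nx, ny)
  c1 <- makeCoilMaps(grid, 1)
  fs <- fullSampling(grid, 1)
  ksp <- DynamicKSpace(grid, fs$samp, list(matrix(0i, nx * ny, 1)))
  set.seed(16)
  y1 <- list(matrix(rcplx(nx * ny), nx * ny, 1))
  y2 <- list(matrix(rcplx(nx * ny), nx * ny, 1))
  a1 <- adjointSignal(y1, c1, ksp)
  a2 <- adjointSignal(y2, c1, ksp)
  a12 <- adjointSignal(list(3 * y1[[1]] + y2[[1]]), c1, ksp)
  expect_lt(max(Mod(a12 - 3 * a1 - a2)), 1e-10)
  # D = 0, full sampling, uniform coil: scaled inverse FFT
  ref <- fft(matrix(y1[[1]], nx, ny), inverse = TRUE) / sqrt(nx * ny)
  expect_lt(max(Mod(matrix(a1, nx, ny) - ref)), 1e-10)
})

test_that("temporal Fourier operator is unitary", {
  set.seed(17)
  X <- matrix(rcplx(40 * 7), 40, 7)
  expect_lt(max(Mod(temporalFourierAdjoint(temporalFourier(X)) - X)), 1e-12)
  # Parseval
  expect_equal(sum(Mod(temporalFourier(X))^2), sum(Mod(X)^2),
               tolerance = 1e-12)
  # a static series concentrates all energy in the DC bin
  S <- matrix(rcplx(40), 40, 1)[, rep(1, 8)]
  TS <- temporalFourier(S)
  expect_lt(max(Mod(TS[, -1])), 1e-10)
})

test_that("spectral norm estimates match dense linear algebra", {
  # identity and diagonal operators
  idf <- function(x) x
  expect_equal(as.numeric(spectralNorm(idf, idf, matrix(0i, 5, 1))), 1,
               tolerance = 1e-6)
  dg <- c(4, 1)
  dop <- function(x) dg * x
  expect_equal(as.numeric(spectralNorm(dop, dop, matrix(0i, 2, 1))), 16,
               tolerance = 1e-3)
  # random complex matrix: largest eigenvalue of A^H A from dense SVD
  set.seed(18)
  A <- matrix(rcplx(32 * 32), 32, 32)
  fwd <- function(x) A %*% x
  adj <- function(y) Conj(t(A)) %*% y
  est <- spectralNorm(fwd, adj, matrix(0i, 32, 1), tol = 1e-9,
                      maxIter = 2000)
  expect_equal(as.numeric(est), max(svd(A)$d)^2, tolerance = 1e-3)
})
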