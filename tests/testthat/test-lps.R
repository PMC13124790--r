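# proximal operators against dense/brute-force oracles, and the FISTA
# image-reconstruction step

test_that("singular value thresholding matches the dense SVD oracle", {
  X <- diag(c(5, 3, 1)) + 0i
  expect_equal(sort(svd(svt(X, 2))$d), c(0, 1, 3), tolerance = 1e-8)
  set.seed(20)
  A <- matrix(rcplx(8 * 6), 8, 6)
  s <- svd(A)
  tau <- s$d[3]
  oracle <- s$u %*% (pmax(s$d - tau, 0) * Conj(t(s$v)))
  expect_lt(max(Mod(svt(A, tau) - oracle)), 1e-8)
  expect_identical(svt(A, 0), A)
  expect_lt(max(Mod(svt(A, max(s$d) + 1))), 1e-12)
  expect_error(svt(A, -1), "tau")
})

test_that("hard rank truncation is the best low-rank approximation", {
  set.seed(21)
  A <- matrix(rcplx(8 * 6), 8, 6)
  s <- svd(A)
  for (R in c(1, 2, 4)) {
    tr <- hardRankTruncate(A, R)
    # Frobenius error equals the root of the tail singular value energy
    expect_equal(sqrt(sum(Mod(A - tr)^2)),
                 sqrt(sum(s$d[-seq_len(R)]^2)), tolerance = 1e-8)
  }
  # rank >= rank(X) leaves X unchanged; static series is exactly rank 1
  expect_lt(max(Mod(hardRankTruncate(A, 6) - A)), 1e-8)
  static <- matrix(rcplx(8), 8, 1)[, rep(1, 5)]
  expect_lt(max(Mod(hardRankTruncate(static, 1) - static)), 1e-10)
  expect_error(hardRankTruncate(A, 7), "rank")
  # the subspace-iteration path agrees with the dense path
  B <- matrix(rcplx(200 * 30), 200, 30)
  t1 <- hardRankTruncate(B, 2)
  s2 <- svd(B, nu = 2, nv = 2)
  oracle <- s2$u %*% (s2$d[1:2] * Conj(t(s2$v)))
  expect_lt(max(Mod(t1 - oracle)), 1e-6)
})

test_that("temporal-Fourier prox matches per-bin brute-force minimization", {
  # scalar closed form: 3 e^{i theta} thresholded by 2 -> e^{i theta}
  th <- 0.7
  x <- matrix(3 * exp(1i * th), 1, 1)
  expect_equal(proxSparseTF(x, 2)[1, 1], exp(1i * th), tolerance = 1e-12)
  expect_identical(proxSparseTF(x, 0), x)
  expect_error(proxSparseTF(x, -0.1), "tau")

  # 4x4 case: solve argmin_z 0.5 ||z - S||^2 + tau ||T z||_1 numerically,
  # independently, bin by bin in the transform domain
  set.seed(22)
  S <- matrix(rcplx(16), 4, 4)
  tau <- 0.8
  Z <- temporalFourier(S)
  oracleBin <- function(z) {   # exhaustive grid search with refinement;
    # the origin (the kink of the penalty) is always among the candidates
    f <- function(re, im) 0.5 * ((re - Re(z))^2 + (im - Im(z))^2) +
      tau * sqrt(re^2 + im^2)
    c0 <- c(Re(z), Im(z)); half <- max(Mod(z), tau) * 1.5
    for (stage in 1:9) {
      g <- seq(-half, half, length.out = 41)
      re <- c(0, c0[1] + rep(g, times = 41))
      im <- c(0, c0[2] + rep(g, each = 41))
      v <- f(re, im)
      k <- which.min(v)
      c0 <- c(re[k], im[k])
      half <- half * 0.06
    }
    complex(real = c0[1], imaginary = c0[2])
  }
  Zo <- matrix(vapply(Z, oracleBin, complex(1)), 4, 4)
  expect_lt(max(Mod(proxSparseTF(S, tau) - temporalFourierAdjoint(Zo))),
            1e-6)
})

test_that("the image step recovers fully sampled data as lambda -> 0", {
  tr <- cached("staticPhantomL",
               generatePhantom(quickPhantom(nx = 32, ny = 32, frames = 10,
                                            cardiacContraction = 0.35)))
  c1 <- makeCoilMaps(tr@motion@grid, 1)
  ksp <- simulateKspace(tr, c1, fullSampling(tr@motion@grid, 10), sigma = 0)
  rc <- ReconConfig(lambdaS = 1e-12, lambdaL = 1e-12, rankL = NA,
                    maxIterLps = 80, normalizeData = FALSE)
  ref <- solveLps(ksp, c1, NULL, rc)
  Q <- referenceImages(ref)
  expect_lt(sqrt(sum(Mod(Q - tr@frames)^2) / sum(tr@frames^2)), 1e-3)
})

test_that("a static series yields a static rank-1 L with S shrunk away", {
  tr <- cached("staticPhantom32",
               generatePhantom(quickPhantom(nx = 32, ny = 32, frames = 10,
                                            cardiacContraction = 0,
                                            respAmplitude = 0,
                                            rvOnset = 9, lvOnset = 9.5,
                                            myoOnset = 9.9)))
  c1 <- makeCoilMaps(tr@motion@grid, 2)
  ksp <- simulateKspace(tr, c1, fullSampling(tr@motion@grid, 10), sigma = 0)
  rc <- ReconConfig(lambdaS = 1e4, rankL = 1, maxIterLps = 60,
                    normalizeData = FALSE)
  ref <- solveLps(ksp, c1, NULL, rc)
  expect_lt(max(Mod(ref@S)), 1e-6)
  # L approximates the static frames (all frames identical)
  relerr <- sqrt(sum(Mod(ref@L - tr@frames)^2) / sum(tr@frames^2))
  expect_lt(relerr, 0.02)
  # Q = L + S exactly by construction
  expect_identical(referenceImages(ref), ref@L + ref@S)
})

test_that("the objective decreases and the trace is well-formed", {
  ksp <- cached("lpsKsp", {
    tr <- generatePhantom(quickPhantom(nx = 32, ny = 32, frames = 10))
    co <- makeCoilMaps(tr@motion@grid, 2)
    simulateKspace(tr, co,
                   list(scheme = "cartesian-lines",
                        samp = lapply(1:10, function(t)
                          makeSampling("cartesian_pseudorandom", t, 8,
                                       tr@motion@grid, 3))))
  })
  co <- makeCoilMaps(ksp@grid, 2)
  rc <- ReconConfig(lambdaS = 10, rankL = 1, maxIterLps = 40,
                    normalizeData = FALSE)
  ref <- solveLps(ksp, co, NULL, rc)
  tr0 <- attr(ref, "trace")
  expect_true(all(is.finite(tr0$objective)))
  expect_gt(tr0$gamma, 0)
  # exact objective at the solution does not exceed the zero-start value
  zero <- ReferenceSeries(matrix(0i, nVoxels(ksp@grid), 10),
                          matrix(0i, nVoxels(ksp@grid), 10), ksp@grid)
  o0 <- lpsObjective(zero, co, ksp, NULL, rc)$value
  oF <- lpsObjective(ref, co, ksp, NULL, rc)$value
  expect_lt(oF, o0)
})
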