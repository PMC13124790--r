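# motion estimation: TV, analytic gradients, parameter recovery, frequency
# disentanglement

test_that("motion TV matches brute-force evaluation and is homogeneous", {
  nx <- 4; ny <- 4
  grid <- ImageGrid(8, 8)  # grid validity needs >= 8; use direct arrays
  D <- array(0, c(8, 8, 2, 1))
  mot <- MotionFieldStack(D, grid)
  expect_equal(tvMotion(mot), 0)
  expect_equal(tvMotion(mot, "printed"), 0)

  # single-voxel unit step in Dx: brute-force discrete formula
  D[3, 3, 1, 1] <- 1
  mot <- MotionFieldStack(D, grid)
  brute <- 0
  for (j in 1:8) for (i in 1:8) {
    gx <- if (i < 8) D[i + 1, j, 1, 1] - D[i, j, 1, 1] else 0
    gy <- if (j < 8) D[i, j + 1, 1, 1] - D[i, j, 1, 1] else 0
    gx2 <- if (i < 8) D[i + 1, j, 2, 1] - D[i, j, 2, 1] else 0
    gy2 <- if (j < 8) D[i, j + 1, 2, 1] - D[i, j, 2, 1] else 0
    brute <- brute + sqrt(gx^2 + gy^2 + gx2^2 + gy2^2)
  }
  expect_equal(tvMotion(mot), brute, tolerance = 1e-12)

  # homogeneity |a| TV(D), both variants
  set.seed(30)
  Dr <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  m1 <- MotionFieldStack(Dr, grid)
  m2 <- MotionFieldStack(-2.5 * Dr, grid)
  expect_equal(tvMotion(m2), 2.5 * tvMotion(m1), tolerance = 1e-10)
  expect_equal(tvMotion(m2, "printed"), 2.5 * tvMotion(m1, "printed"),
               tolerance = 1e-10)
  # the printed variant never exceeds the mixed norm times sqrt(2) and is
  # below the componentwise sum
  expect_lte(tvMotion(m1, "printed"), sqrt(2) * tvMotion(m1))
})

test_that("analytic motion gradients match central finite differences", {
  set.seed(31)
  nx <- 16; ny <- 16; M <- 6; C <- 2
  grid <- ImageGrid(nx, ny)
  coils <- makeCoilMaps(grid, C)
  Q <- matrix(rcplx(nx * ny * M), nx * ny, M)

  configs <- list(
    list(ksp = tinyKspace(nx, ny, M, C, 6, seed = 32, randomData = TRUE),
         ctrlT = NA),                       # Cartesian lines, dense temporal
    list(ksp = {
      set.seed(33)
      samp <- lapply(seq_len(M), function(t) sort(sample(nx * ny, 70)))
      DynamicKSpace(grid, samp, lapply(seq_len(M), function(t)
        matrix(rcplx(70 * C), 70, C)), scheme = "gridded-points")
    }, ctrlT = 4))                          # gridded points, temporal spline

  for (cc in configs) {
    nct <- if (is.na(cc$ctrlT)) M else cc$ctrlT
    model <- LowRankMotionModel(
      phi = matrix(rnorm(2 * 36 * 2, 0, 0.3), 72, 2),
      psi = matrix(rnorm(nct * 2, 0, 0.5), nct, 2),
      ctrl = 6, frames = M, grid = grid, ctrlT = cc$ctrlT)
    lam <- 0.5
    obj <- motionObjective(model, Q, cc$ksp, coils, lam)
    valOnly <- function(m)
      motionObjective(m, Q, cc$ksp, coils, lam, wantGrad = FALSE)$value
    h <- 1e-5
    idxP <- sample(length(model@phi), 12)
    idxS <- sample(length(model@psi), 8)
    for (i in idxP) {
      m1 <- model; m2 <- model
      m1@phi[i] <- m1@phi[i] + h; m2@phi[i] <- m2@phi[i] - h
      fd <- (valOnly(m1) - valOnly(m2)) / (2 * h)
      expect_lt(abs(obj$gradPhi[i] - fd) / max(abs(fd), 1e-6), 1e-4)
    }
    for (i in idxS) {
      m1 <- model; m2 <- model
      m1@psi[i] <- m1@psi[i] + h; m2@psi[i] <- m2@psi[i] - h
      fd <- (valOnly(m1) - valOnly(m2)) / (2 * h)
      expect_lt(abs(obj$gradPhi[1] * 0 + obj$gradPsi[i] - fd) /
                  max(abs(fd), 1e-6), 1e-4)
    }
  }
})

test_that("objective structure: zero image and scale ambiguity", {
  set.seed(34)
  nx <- 16; ny <- 16; M <- 4; C <- 2
  grid <- ImageGrid(nx, ny)
  coils <- makeCoilMaps(grid, C)
  ksp <- tinyKspace(nx, ny, M, C, 5, seed = 35, randomData = TRUE)
  model <- LowRankMotionModel(phi = matrix(rnorm(72, 0, 0.3), 72, 1),
                              psi = matrix(rnorm(M), M, 1),
                              ctrl = 6, frames = M, grid = grid)
  # zero reference image: data term is the data energy, data gradient 0
  o <- motionObjective(model, matrix(0i, nx * ny, M), ksp, coils, 0.3)
  expect_equal(o$dataTerm,
               sum(vapply(ksp@samples, function(s) sum(Mod(s)^2),
                          numeric(1))), tolerance = 1e-10)
  tvOnly <- tvMotion(expandMotion(model))
  expect_equal(o$value, o$dataTerm + 0.3 * tvOnly, tolerance = 1e-8)

  # scale ambiguity phi -> a phi, psi -> psi / a leaves the objective fixed
  Q <- matrix(rcplx(nx * ny * M), nx * ny, M)
  o1 <- motionObjective(model, Q, ksp, coils, 0.3, wantGrad = FALSE)$value
  m2 <- model; m2@phi <- model@phi * 2; m2@psi <- model@psi / 2
  o2 <- motionObjective(m2, Q, ksp, coils, 0.3, wantGrad = FALSE)$value
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("motion recovery: translation and null experiments", {
  # translation phantom, 3 voxels, fully sampled, noiseless
  cfgT <- quickPhantom(frames = 24, cardiacContraction = 0,
                       respAmplitude = 3, respPeriod = 1.2)
  trT <- generatePhantom(cfgT)
  co <- makeCoilMaps(trT@motion@grid, 4)
  kspT <- simulateKspace(trT, co, fullSampling(trT@motion@grid, 24),
                         sigma = 0)
  rc <- ReconConfig(rankD = 1, ctrlX = 24, ctrlY = 24, lambdaTV = 1e-8,
                    seed = 5)
  m <- solveMotion(trT@refFrames, kspT, co, rc)
  Dref <- rereferenceMotion(expandMotion(m), 1)
  myo <- trT@labels == 2
  expect_lt(epe(Dref, trT@motion, mask = myo)$mean, 0.3)

  # zero-motion phantom: displacement RMS below 0.1 voxel
  cfg0 <- quickPhantom(frames = 16, cardiacContraction = 0)
  tr0 <- generatePhantom(cfg0)
  ksp0 <- simulateKspace(tr0, co, fullSampling(tr0@motion@grid, 16),
                         sigma = 0)
  m0 <- solveMotion(tr0@refFrames, ksp0, co,
                    ReconConfig(rankD = 1, ctrlX = 24, ctrlY = 24, seed = 3))
  expect_lt(sqrt(mean(expandMotion(m0)@D^2)), 0.1)

  # determinism: same seed, same result
  m0b <- solveMotion(tr0@refFrames, ksp0, co,
                     ReconConfig(rankD = 1, ctrlX = 24, ctrlY = 24, seed = 3))
  expect_identical(m0@phi, m0b@phi)
  expect_identical(m0@psi, m0b@psi)
})

test_that("frequency split partitions two-tone motion and respects edge cases", {
  ds <- cached("twoTone", {
    cfg <- quickPhantom(frames = 150, nCoils = 4, heartPeriod = 1,
                        respAmplitude = 2, respPeriod = 4,
                        rvOnset = 1, lvOnset = 2, myoOnset = 3)
    tr <- generatePhantom(cfg)
    co <- makeCoilMaps(tr@motion@grid, 4)
    ksp <- simulateKspace(tr, co, fullSampling(tr@motion@grid, 150),
                          sigma = 0)
    m <- solveMotion(tr@refFrames, ksp, co,
                     ReconConfig(rankD = 2, ctrlX = 24, ctrlY = 24,
                                 seed = 4, maxIterMotion = 150L))
    list(truth = tr, model = m)
  })
  fs <- frequencySplit(ds$model, 0.5, 0.05)
  expect_length(fs$low, 1)
  expect_length(fs$high, 1)
  expect_lt(fs$dominantHz[fs$low], 0.5)
  expect_gt(fs$dominantHz[fs$high], 0.5)
  # group field stacks add up to the full expansion
  full <- expandMotion(ds$model)@D
  expect_equal(fs$lowFields@D + fs$highFields@D, full, tolerance = 1e-10)

  # sign flips leave the partition unchanged
  m2 <- ds$model
  m2@phi[, 1] <- -m2@phi[, 1]; m2@psi[, 1] <- -m2@psi[, 1]
  fs2 <- frequencySplit(m2, 0.5, 0.05)
  expect_identical(fs2$low, fs$low)
  expect_identical(fs2$high, fs$high)

  # a static component lands in the low group
  grid <- ImageGrid(16, 16)
  ms <- LowRankMotionModel(phi = matrix(1, 2 * 36, 1),
                           psi = matrix(1, 20, 1), ctrl = 6,
                           frames = 20, grid = grid)
  fss <- frequencySplit(ms, 0.5, 0.05)
  expect_identical(fss$low, 1L)
  expect_length(fss$high, 0)
  expect_error(frequencySplit(ms, 20, 0.05), "Nyquist")
})
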