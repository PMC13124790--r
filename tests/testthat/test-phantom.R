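# phantom generator: signal model, kinetics, geometry/motion consistency,
# coil maps, sampling patterns, k-space simulation

test_that("saturation-recovery signal follows the closed form and limits", {
  # direct evaluation (units cancel in Tsat/T1)
  expect_equal(saturationRecoverySignal(1, 1000, 150, 15),
               sin(15 * pi / 180) * (1 - exp(-0.15)))
  # limits: long T1 kills the signal, long Tsat saturates to M0 sin(flip)
  expect_lt(saturationRecoverySignal(1, 1e9, 150, 15), 1e-6)
  expect_equal(saturationRecoverySignal(2, 1000, 1e7, 90), 2, tolerance = 1e-9)
  # monotonicity
  s <- saturationRecoverySignal(1, c(500, 1000, 2000), 150, 15)
  expect_true(all(diff(s) < 0))
  expect_error(saturationRecoverySignal(1, -1, 150, 15), "T1")
  expect_error(saturationRecoverySignal(1, 1000, 0, 15), "Tsat")
})

test_that("gamma-variate bolus has first-pass ordering and exact area", {
  cfg <- PhantomConfig()
  t <- seq(0, 40, by = 0.05)
  crv <- bolusConcentration(t, "rv", cfg)
  clv <- bolusConcentration(t, "lv", cfg)
  cmy <- bolusConcentration(t, "myo", cfg)
  # zero before onset
  expect_true(all(crv[t < cfg@rvOnset] == 0))
  expect_true(all(clv[t < cfg@lvOnset] == 0))
  # peak ordering RV -> LV -> myocardium
  expect_lt(t[which.max(crv)], t[which.max(clv)])
  expect_lt(t[which.max(clv)], t[which.max(cmy)])
  # area under the LV curve matches the closed-form gamma integral:
  # A exp(a) (a b)^-a b^(a+1) Gamma(a+1)
  a <- cfg@bolusShape; b <- cfg@bolusScale
  A <- cfg@peakConc[["lv"]]
  closed <- A * exp(a) * (a * b)^(-a) * b^(a + 1) * gamma(a + 1)
  quad <- stats::integrate(function(u) bolusConcentration(u, "lv", cfg),
                           cfg@lvOnset, Inf, rel.tol = 1e-9)$value
  expect_equal(quad, closed, tolerance = 1e-6)
  expect_error(bolusConcentration(1, "lv", PhantomConfig(bolusShape = -1)))
})

test_that("default phantom reproduces the configured acquisition geometry", {
  cfg <- PhantomConfig()
  expect_equal(cfg@frames, 600L)
  expect_equal(cfg@nx, 100L); expect_equal(cfg@ny, 100L)
  expect_equal(cfg@dt, 0.05)
  expect_equal(cfg@heartPeriod / cfg@dt, 20)   # 1 s cycle at 50 ms
  expect_equal(cfg@Tsat, 0.150)
  expect_equal(cfg@flip, 15)
  expect_equal(cfg@nCoils, 8L)
  expect_equal(cfg@readouts, 12L)

  tr <- generatePhantom(quickPhantom(frames = 21))
  # heart period 20 frames: frame 21 is one full cycle after frame 1
  expect_equal(tr@motion@D[, , , 21], tr@motion@D[, , , 1], tolerance = 1e-12)
  expect_equal(max(abs(tr@motion@D[, , , 1])), 0)   # frame 1 is rest
})

test_that("zero-amplitude phantom is static except for enhancement", {
  tr <- cached("staticPhantom",
               generatePhantom(quickPhantom(frames = 8,
                                            cardiacContraction = 0,
                                            respAmplitude = 0)))
  expect_equal(max(abs(tr@motion@D)), 0)
  expect_identical(tr@frames, tr@refFrames)
  expect_true(all(tr@labels == tr@labels[, , rep(1, 8)]))
  # frames still differ because of the bolus (early upslope of the RV curve)
  expect_gt(max(abs(tr@frames[, 8] - tr@frames[, 1])), 0.002)
})

test_that("phantom determinism and FOV containment guard", {
  c1 <- quickPhantom(frames = 5, noiseSigma = NA)
  expect_identical(generatePhantom(c1)@frames, generatePhantom(c1)@frames)
  expect_error(generatePhantom(quickPhantom(respAmplitude = 30)),
               "field of view")
})

test_that("warping frame-1 labels by the true fields matches analytic labels", {
  # full protocol geometry: the myocardial annulus is ~6 voxels wide there,
  # so nearest-neighbor discretization noise stays small
  tr <- generatePhantom(quickPhantom(nx = 100, ny = 100, frames = 8,
                                     respAmplitude = 1, respPeriod = 0.4))
  myo <- tr@labels == 2
  warped <- warpSegmentation(matrix(as.integer(myo[, , 1]), 100, 100),
                             tr@motion)
  dice <- vapply(seq_len(8), function(t)
    diceCoefficient(warped[, , t], myo[, , t]), numeric(1))
  expect_true(all(dice >= 0.95))
})

test_that("coil maps are smooth, deterministic and jointly cover the body", {
  grid <- ImageGrid(48, 48)
  cm <- makeCoilMaps(grid, 8)
  expect_identical(cm@maps, makeCoilMaps(grid, 8)@maps)
  expect_error(makeCoilMaps(grid, 0), "coil")
  # single coil is uniform (plain Fourier sampling)
  expect_true(all(makeCoilMaps(grid, 1)@maps == 1 + 0i))
  # root-sum-of-squares over the body support stays well above zero
  tr <- cached("staticPhantom",
               generatePhantom(quickPhantom(frames = 8,
                                            cardiacContraction = 0,
                                            respAmplitude = 0)))
  body <- matrix(tr@labels[, , 1] > 0, 48, 48)
  rss <- sqrt(apply(Mod(cm@maps)^2, c(1, 2), sum))
  expect_gt(min(rss[body]), 0.1 * max(rss))
})

test_that("Cartesian sampling draws the configured number of lines", {
  grid <- ImageGrid(100, 100)
  for (t in c(1, 7, 33)) {
    l <- makeSampling("cartesian_pseudorandom", t, 12, grid, seed = 4)
    expect_length(unique(l), 12)
    expect_true(all(l >= 1 & l <= 100))
    # the fixed low-frequency core (bins around DC) is always present
    expect_true(all(c(1L, 2L, 100L) %in% l))
  }
  # patterns are re-drawn per frame but reproducible
  expect_identical(makeSampling("cartesian_pseudorandom", 3, 12, grid, 4),
                   makeSampling("cartesian_pseudorandom", 3, 12, grid, 4))
  expect_false(identical(
    makeSampling("cartesian_pseudorandom", 3, 12, grid, 4),
    makeSampling("cartesian_pseudorandom", 4, 12, grid, 4)))
  # full sampling
  expect_identical(makeSampling("cartesian_pseudorandom", 1, 100, grid, 1),
                   1:100)
  expect_error(makeSampling("cartesian_pseudorandom", 1, 101, grid, 1),
               "lines")
})

test_that("radial spokes advance by the golden angle and grid to k-space", {
  grid <- ImageGrid(64, 64)
  golden <- 111.246
  # successive global spoke indices differ by the golden angle mod 180
  angles <- (0:9 * golden) %% 180
  diffs <- diff(angles) %% 180
  expect_true(all(abs(diffs - golden %% 180) < 1e-9 |
                    abs(diffs - (golden %% 180 - 180)) %% 180 < 1e-9))
  s1 <- makeSampling("radial_golden_angle", 1, 10, grid, seed = 1)
  s2 <- makeSampling("radial_golden_angle", 2, 10, grid, seed = 1)
  expect_true(all(s1 >= 1 & s1 <= 64 * 64))
  expect_false(identical(s1, s2))   # angles continue across frames
  # a spoke has about one sample per radius step after gridding
  expect_gt(length(s1), 300)

  # the radial presets simulate through the gridded-points pathway
  ds <- simulatePerfusionDataset(phantomPreset("test3", nx = 32, ny = 32,
                                               frames = 3, nCoils = 2,
                                               rvOnset = 0.05, lvOnset = 0.1,
                                               myoOnset = 0.15))
  expect_identical(ds$kspace@scheme, "gridded-points")
  expect_s4_class(ds$kspace, "DynamicKSpace")
})

test_that("k-space simulation is exact, masked, and noise scales correctly", {
  tr <- cached("staticPhantom",
               generatePhantom(quickPhantom(frames = 8,
                                            cardiacContraction = 0,
                                            respAmplitude = 0)))
  grid <- tr@motion@grid
  c1 <- makeCoilMaps(grid, 1)
  full <- fullSampling(grid, 8)
  ksp <- simulateKspace(tr, c1, full, sigma = 0)
  # sigma = 0, full sampling, uniform coil: inverse FFT recovers frames
  rec <- adjointSignal(ksp@samples, c1, ksp)
  expect_lt(max(Mod(rec - tr@frames)), 1e-10)

  # undersampled output contains exactly the sampled lines
  us <- list(scheme = "cartesian-lines",
             samp = replicate(8, c(1L, 5L, 9L), simplify = FALSE))
  k2 <- simulateKspace(tr, c1, us, sigma = 0)
  expect_equal(nrow(k2@samples[[1]]), 48 * 3)

  # doubling sigma doubles the residual RMS against noiseless samples
  k3 <- simulateKspace(tr, c1, full, sigma = 0.01, seed = 5)
  k4 <- simulateKspace(tr, c1, full, sigma = 0.02, seed = 6)
  r3 <- sqrt(mean(Mod(k3@samples[[1]] - ksp@samples[[1]])^2))
  r4 <- sqrt(mean(Mod(k4@samples[[1]] - ksp@samples[[1]])^2))
  expect_equal(r4 / r3, 2, tolerance = 0.05)
  # determinism under a fixed seed
  k5 <- simulateKspace(tr, c1, full, sigma = 0.01, seed = 5)
  expect_identical(k3@samples, k5@samples)
  expect_error(simulateKspace(tr, c1, full, sigma = -1), "sigma")
})
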