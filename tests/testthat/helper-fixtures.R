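# Shared fixtures: tiny deterministic problems built in code.

rcplx <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))

# small random k-space geometry (pattern only; samples optionally zero)
tinyKspace <- function(nx = 16, ny = 16, M = 6, C = 2, linesPerFrame = 5,
                       seed = 1, randomData = FALSE) {
  set.seed(seed)
  grid <- ImageGrid(nx, ny)
  samp <- lapply(seq_len(M), function(t) sort(sample(ny, linesPerFrame)))
  samples <- lapply(seq_len(M), function(t) {
    n <- nx * linesPerFrame
    if (randomData) matrix(rcplx(n * C), n, C) else matrix(0i, n, C)
  })
  DynamicKSpace(grid, samp, samples)
}

# smooth random motion fields
tinyMotion <- function(nx = 16, ny = 16, M = 6, sd = 0.4, seed = 1) {
  set.seed(seed)
  MotionFieldStack(array(rnorm(nx * ny * 2 * M, 0, sd), c(nx, ny, 2, M)),
                   ImageGrid(nx, ny))
}

# fast phantom configuration for solver tests (bolus sped up to fit short
# acquisitions); any default can be overridden
quickPhantom <- function(...) {
  args <- utils::modifyList(
    list(nx = 48, ny = 48, frames = 24, nCoils = 4, noiseSigma = 0,
         dt = 0.05, rvOnset = 0.1, lvOnset = 0.3, myoOnset = 0.5),
    list(...))
  do.call(PhantomConfig, args)
}

# caches shared across test files (heavy experiments computed once)
.testCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.testCache[[key]])) .testCache[[key]] <- force(expr)
  .testCache[[key]]
}
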