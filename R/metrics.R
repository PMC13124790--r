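# Quantitative validation: SSIM, end-point error, DICE via warped
# segmentations, and Tenengrad sharpness. Metrics never mutate their inputs.

# Gaussian filter matching the common reference implementation:
# sigma = 1.5, kernel radius floor(truncate*sigma + 0.5) with truncate = 3.5
# (11 x 11 window), 'reflect' boundary
.ssimFilter <- function(img, sigma = 1.5, truncate = 3.5) {
  r <- floor(truncate * sigma + 0.5)
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  sm1 <- function(m) {
    n <- nrow(m)
    out <- m * k[r + 1]
    for (o in 1:r) {
      idxu <- seq_len(n) + o; idxu[idxu > n] <- 2 * n + 1 - idxu[idxu > n]
      idxd <- seq_len(n) - o; idxd[idxd < 1] <- 1 - idxd[idxd < 1]
      out <- out + k[r + 1 + o] * m[idxu, , drop = FALSE] +
        k[r + 1 - o] * m[idxd, , drop = FALSE]
    }
    out
  }
  t(sm1(t(sm1(img))))
}

# SSIM map of two real images in [0, dataRange]
.ssimMap <- function(x, y, dataRange = 1, K1 = 0.01, K2 = 0.03,
                     sigma = 1.5) {
  winSize <- 2 * floor(3.5 * sigma + 0.5) + 1
  NP <- winSize^2
  covNorm <- NP / (NP - 1)          # sample covariance
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  ux <- .ssimFilter(x, sigma); uy <- .ssimFilter(y, sigma)
  uxx <- .ssimFilter(x * x, sigma); uyy <- .ssimFilter(y * y, sigma)
  uxy <- .ssimFilter(x * y, sigma)
  vx <- covNorm * (uxx - ux * ux)
  vy <- covNorm * (uyy - uy * uy)
  vxy <- covNorm * (uxy - ux * uy)
  ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
}

#' Structural similarity of a dynamic series
#'
#' Mean SSIM per frame against a reference series. Magnitudes of both series
#' are jointly normalized to [0, 1] (one common scale), then the standard
#' SSIM with an 11 x 11 Gaussian window (sigma 1.5, K1 = 0.01, K2 = 0.03)
#' is computed; the mean is taken over the mask intersected with the
#' window-interior region.
#'
#' @param H,Href complex or real matrices (voxels x frames), or
#'   [CineSeries-class]/[ReferenceSeries-class] objects.
#' @param grid an [ImageGrid-class] (taken from `H` when it is a series
#'   object).
#' @param mask logical nx-by-ny matrix, an (nx, ny, frames) array, or NULL
#'   for the whole frame.
#' @return list with `perFrame`, `mean`, `sd`.
#' @export
ssimSeries <- function(H, Href, grid = NULL, mask = NULL) {
  if (is(H, "CineSeries")) { grid <- H@grid; H <- H@H }
  if (is(H, "ReferenceSeries")) { grid <- H@grid; H <- referenceImages(H) }
  if (is(Href, "CineSeries")) Href <- Href@H
  if (is(Href, "ReferenceSeries")) Href <- referenceImages(Href)
  stopifnot(identical(dim(H), dim(Href)), !is.null(grid))
  nx <- grid@nx; ny <- grid@ny; M <- ncol(H)
  A <- Mod(H); B <- Mod(Href)
  scale <- max(A, B)
  if (scale > 0) { A <- A / scale; B <- B / scale }
  pad <- 5L
  interior <- matrix(FALSE, nx, ny)
  interior[(pad + 1):(nx - pad), (pad + 1):(ny - pad)] <- TRUE
  perFrame <- vapply(seq_len(M), function(t) {
    S <- .ssimMap(matrix(A[, t], nx, ny), matrix(B[, t], nx, ny))
    m <- if (is.null(mask)) interior
    else if (length(dim(mask)) == 3L) mask[, , t] & interior
    else mask & interior
    if (!any(m)) stop("empty mask")
    mean(S[m])
  }, numeric(1))
  list(perFrame = perFrame, mean = mean(perFrame), sd = sd(perFrame))
}

#' End-point error of motion fields
#'
#' Per-voxel Euclidean distance between predicted and ground-truth
#' displacement vectors, averaged over the mask per frame:
#' `EPE = sqrt((Dx_pred - Dx_true)^2 + (Dy_pred - Dy_true)^2)`.
#'
#' @param pred,truth [MotionFieldStack-class] objects of equal shape.
#' @param mask logical nx-by-ny matrix, an (nx, ny, frames) array, or NULL
#'   for the whole field of view.
#' @return list with `perFrame` (voxels), `mean`, `sd`, and `meanMm`
#'   (spacing-weighted).
#' @export
epe <- function(pred, truth, mask = NULL) {
  stopifnot(identical(dim(pred@D), dim(truth@D)))
  d <- dim(pred@D); M <- d[4]
  g <- pred@grid
  perFrame <- numeric(M); perFrameMm <- numeric(M)
  for (t in seq_len(M)) {
    ex <- pred@D[, , 1L, t] - truth@D[, , 1L, t]
    ey <- pred@D[, , 2L, t] - truth@D[, , 2L, t]
    e <- sqrt(ex^2 + ey^2)
    eMm <- sqrt((ex * g@dx)^2 + (ey * g@dy)^2)
    m <- if (is.null(mask)) TRUE
    else if (length(dim(mask)) == 3L) mask[, , t] else mask
    perFrame[t] <- mean(e[m]); perFrameMm[t] <- mean(eMm[m])
  }
  list(perFrame = perFrame, mean = mean(perFrame), sd = sd(perFrame),
       meanMm = mean(perFrameMm))
}

#' DICE overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` for two binary masks; returns 1 when
#' both masks are empty (documented convention).
#'
#' @param a,b binary (logical or 0/1) arrays of equal shape.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Warp a segmentation through motion fields
#'
#' Pull-back warp of an integer label map with nearest-neighbor
#' interpolation and no Jacobian weighting (labels are categories, not
#' densities): the label at voxel r and frame t is the source label at
#' `round(r + D_t(r))`, or 0 (background) outside the field of view.
#'
#' @param labels integer nx-by-ny label map (the frame the fields refer to).
#' @param motion a [MotionFieldStack-class].
#' @return integer array (nx, ny, frames).
#' @export
warpSegmentation <- function(labels, motion) {
  if (!all(labels == round(labels))) stop("labels must be integer-valued")
  nx <- dim(labels)[1]; ny <- dim(labels)[2]
  M <- dim(motion@D)[4]
  xs <- rep(0:(nx - 1), times = ny)
  ys <- rep(0:(ny - 1), each = nx)
  out <- array(0L, c(nx, ny, M))
  for (t in seq_len(M)) {
    px <- round(xs + as.vector(motion@D[, , 1L, t]))
    py <- round(ys + as.vector(motion@D[, , 2L, t]))
    ok <- px >= 0 & px < nx & py >= 0 & py < ny
    v <- integer(nx * ny)
    v[ok] <- labels[cbind(px[ok] + 1L, py[ok] + 1L)]
    out[, , t] <- v
  }
  out
}

#' Tenengrad sharpness
#'
#' Reference-free gradient-based sharpness: the mean squared Sobel gradient
#' magnitude over the one-pixel-interior of the magnitude image (no
#' threshold). Homogeneous of degree 2 in the image scale.
#'
#' @param img real or complex image matrix.
#' @return scalar sharpness value.
#' @export
tenengrad <- function(img) {
  x <- Mod(img)
  nx <- nrow(x); ny <- ncol(x)
  if (nx < 3 || ny < 3) stop("image too small")
  i <- 2:(nx - 1); j <- 2:(ny - 1)
  gx <- (x[i + 1, j - 1] + 2 * x[i + 1, j] + x[i + 1, j + 1] -
           x[i - 1, j - 1] - 2 * x[i - 1, j] - x[i - 1, j + 1])
  gy <- (x[i - 1, j + 1] + 2 * x[i, j + 1] + x[i + 1, j + 1] -
           x[i - 1, j - 1] - 2 * x[i, j - 1] - x[i + 1, j - 1])
  mean(gx^2 + gy^2)
}

#' Evaluate a reconstruction against phantom ground truth
#'
#' Computes the standard report: mean SSIM of the cine against the
#' noiseless truth frames (myocardium mask and whole field of view),
#' mean end-point error of the estimated fields re-referenced to frame 1
#' (whole FOV and myocardium), the temporal mean DICE of the warped frame-1
#' myocardium segmentation, and the mean Tenengrad sharpness of the cine.
#'
#' @param result output list of [runCmrMotus()].
#' @param truth a [PhantomTruth-class].
#' @return a JSON-serializable list of summaries.
#' @export
evaluateRecon <- function(result, truth) {
  grid <- truth@motion@grid
  M <- frameCount(truth)
  Htrue <- truth@frames
  myo <- truth@labels == .LBL[["myo"]]
  out <- list()
  out$ssimMyocardium <- ssimSeries(result$cine, Htrue, grid = grid,
                                   mask = myo)[c("mean", "sd", "perFrame")]
  out$ssimFov <- ssimSeries(result$cine, Htrue, grid = grid)[c("mean", "sd")]
  if (!is.null(result$motion)) {
    est <- rereferenceMotion(result$motion, 1L, composed = TRUE)
    out$epeFov <- epe(est, truth@motion)[c("mean", "sd", "meanMm")]
    out$epeMyocardium <- epe(est, truth@motion,
                             mask = myo)[c("mean", "sd", "meanMm")]
    warped <- warpSegmentation(
      matrix(as.integer(myo[, , 1]), grid@nx, grid@ny), est)
    out$diceMyocardium <- list(
      perFrame = vapply(seq_len(M), function(t)
        diceCoefficient(warped[, , t], myo[, , t]), numeric(1)))
    out$diceMyocardium$mean <- mean(out$diceMyocardium$perFrame)
    out$diceMyocardium$sd <- sd(out$diceMyocardium$perFrame)
  }
  out$diceNoMotion <- mean(vapply(seq_len(M), function(t)
    diceCoefficient(myo[, , 1], myo[, , t]), numeric(1)))
  out$tenengrad <- mean(vapply(seq_len(M), function(t)
    tenengrad(matrix(result$cine@H[, t], grid@nx, grid@ny)), numeric(1)))
  out
}
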