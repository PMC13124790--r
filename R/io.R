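# Container I/O (single HDF5 file) and configuration parsing.
#
# Layout (complex data stored as paired real/imag datasets):
#   /meta/{schema,units,seed,scheme}
#   /grid/{nx,ny,dx,dy}
#   /kspace/{nCoils,frames,counts,samp,samplesRe,samplesIm}
#   /coils/{re,im}
#   /truth/{frames,refFrames,dfield,labels,curves,config}   (optional)

.SCHEMA <- "cmrmotus-container-1.0"

.h5writeScalar <- function(x, file, name) rhdf5::h5write(x, file, name)

#' Write a dataset container
#'
#' Writes k-space, coil maps and (optionally) phantom ground truth to a
#' single self-describing HDF5 file, with complex arrays stored as paired
#' real/imag datasets and a schema version plus seed provenance under
#' `/meta`. Refuses to overwrite an existing file unless `overwrite = TRUE`.
#'
#' @param path output file path.
#' @param kspace a [DynamicKSpace-class].
#' @param coils a [CoilMaps-class].
#' @param truth optional [PhantomTruth-class].
#' @param seed integer recorded as provenance (defaults to the truth seed).
#' @param overwrite allow replacing an existing file.
#' @return the path, invisibly.
#' @export
writeContainer <- function(path, kspace, coils, truth = NULL, seed = NA,
                           overwrite = FALSE) {
  validObject(kspace); validObject(coils)
  if (file.exists(path)) {
    if (!overwrite) stop("file exists; use overwrite = TRUE to replace it")
    unlink(path)
  }
  if (is.na(seed) && !is.null(truth)) seed <- truth@config@seed
  g <- kspace@grid
  rhdf5::h5createFile(path)
  for (grp in c("meta", "grid", "kspace", "coils"))
    rhdf5::h5createGroup(path, grp)
  .h5writeScalar(.SCHEMA, path, "meta/schema")
  .h5writeScalar("displacements: voxels; k: cycles/FOV bins", path,
                 "meta/units")
  .h5writeScalar(as.integer(if (is.na(seed)) -1L else seed), path,
                 "meta/seed")
  .h5writeScalar(kspace@scheme, path, "meta/scheme")
  .h5writeScalar(g@nx, path, "grid/nx"); .h5writeScalar(g@ny, path, "grid/ny")
  .h5writeScalar(g@dx, path, "grid/dx"); .h5writeScalar(g@dy, path, "grid/dy")
  .h5writeScalar(kspace@nCoils, path, "kspace/nCoils")
  .h5writeScalar(length(kspace@samp), path, "kspace/frames")
  .h5writeScalar(vapply(kspace@samp, length, 1L), path, "kspace/counts")
  .h5writeScalar(unlist(kspace@samp), path, "kspace/samp")
  allS <- do.call(rbind, kspace@samples)
  .h5writeScalar(Re(allS), path, "kspace/samplesRe")
  .h5writeScalar(Im(allS), path, "kspace/samplesIm")
  .h5writeScalar(Re(coils@maps), path, "coils/re")
  .h5writeScalar(Im(coils@maps), path, "coils/im")
  if (!is.null(truth)) {
    rhdf5::h5createGroup(path, "truth")
    .h5writeScalar(truth@frames, path, "truth/frames")
    .h5writeScalar(truth@refFrames, path, "truth/refFrames")
    .h5writeScalar(truth@motion@D, path, "truth/dfield")
    .h5writeScalar(truth@labels, path, "truth/labels")
    .h5writeScalar(truth@curves, path, "truth/curves")
    .h5writeScalar(yaml::as.yaml(.configToList(truth@config)), path,
                   "truth/config")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a dataset container
#'
#' Reads a file written by [writeContainer()]; validates the schema and all
#' container invariants. The truth block is optional (`truth` is NULL when
#' absent).
#'
#' @param path file path.
#' @return list with `kspace`, `coils`, `truth` (or NULL) and `meta`.
#' @export
readContainer <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ls <- rhdf5::h5ls(path)
  have <- file.path(ls$group, ls$name)
  need <- c("/meta/schema", "/grid/nx", "/kspace/samp", "/kspace/samplesRe",
            "/coils/re")
  if (!all(need %in% have))
    stop("format error: missing datasets: ",
         paste(setdiff(need, have), collapse = ", "))
  rd <- function(name) rhdf5::h5read(path, name)
  schema <- as.character(rd("meta/schema"))
  if (schema != .SCHEMA) stop("format error: unknown schema '", schema, "'")
  grid <- ImageGrid(rd("grid/nx"), rd("grid/ny"), rd("grid/dx"),
                    rd("grid/dy"))
  counts <- as.integer(rd("kspace/counts"))
  sampFlat <- as.integer(rd("kspace/samp"))
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  samp <- lapply(seq_along(counts), function(t) sampFlat[starts[t]:ends[t]])
  scheme <- as.character(rd("meta/scheme"))
  sRe <- rd("kspace/samplesRe"); sIm <- rd("kspace/samplesIm")
  allS <- matrix(complex(real = sRe, imaginary = sIm), nrow(sRe), ncol(sRe))
  perFrame <- if (scheme == "cartesian-lines") grid@nx * counts else counts
  endsS <- cumsum(perFrame); startsS <- endsS - perFrame + 1L
  samples <- lapply(seq_along(counts), function(t)
    allS[startsS[t]:endsS[t], , drop = FALSE])
  kspace <- DynamicKSpace(grid, samp, samples, scheme = scheme)
  cRe <- rd("coils/re"); cIm <- rd("coils/im")
  coils <- CoilMaps(array(complex(real = cRe, imaginary = cIm), dim(cRe)),
                    grid)
  truth <- NULL
  if ("/truth/frames" %in% have) {
    cfg <- .configFromList(yaml::yaml.load(as.character(rd("truth/config"))))
    truth <- new("PhantomTruth", frames = rd("truth/frames"),
                 refFrames = rd("truth/refFrames"),
                 motion = MotionFieldStack(rd("truth/dfield"), grid),
                 labels = array(as.integer(rd("truth/labels")),
                                dim(rd("truth/labels"))),
                 curves = rd("truth/curves"), config = cfg)
  }
  meta <- list(schema = schema, seed = as.integer(rd("meta/seed")),
               scheme = scheme, units = as.character(rd("meta/units")))
  rhdf5::h5closeAll()
  list(kspace = kspace, coils = coils, truth = truth, meta = meta)
}

# PhantomConfig <-> plain list (for YAML round-trips)
.configToList <- function(config) {
  nms <- slotNames(class(config))
  out <- lapply(nms, function(nm) {
    v <- slot(config, nm)
    if (is.numeric(v) && any(is.infinite(v))) v[is.infinite(v)] <- 1e30
    if (!is.null(names(v))) as.list(v) else v
  })
  names(out) <- nms
  out
}

.configFromList <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  for (nm in c("peakConc", "m0", "bulkShift"))
    if (!is.null(lst[[nm]])) lst[[nm]] <- unlist(lst[[nm]])
  if (!is.null(lst$bulkOnset) && lst$bulkOnset >= 1e30) lst$bulkOnset <- Inf
  do.call(PhantomConfig, lst)
}

#' Reconstruction presets
#'
#' Named parameter sets for the four standard experiments:
#' \describe{
#'   \item{test1}{perfusion phantom: lambdaS = 10, lambdaTV = 1e-8, explicit
#'     rank 1 for L and the motion model, 80 spatial control points, dense
#'     temporal coefficients.}
#'   \item{test2}{free-running cine: lambdaS = 1, motion rank 4, 90 spatial
#'     and 40 temporal control points, lambdaTV = 1e-8.}
#'   \item{test3}{breath-hold radial perfusion: lambdaS = 1, motion rank 1,
#'     80 spatial control points, dense temporal, lambdaTV = 1e-7.}
#'   \item{test4}{free-running radial perfusion: lambdaS = 5, motion rank 3,
#'     64 spatial and 150 temporal control points, lambdaTV = 1e-8.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to [ReconConfig()].
#' @return a [ReconConfig-class].
#' @export
reconPreset <- function(name = c("test1", "test2", "test3", "test4"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    test1 = list(lambdaS = 10, lambdaTV = 1e-8, rankL = 1L, rankD = 1L,
                 ctrlX = 80L, ctrlY = 80L, ctrlT = NA_integer_),
    test2 = list(lambdaS = 1, lambdaTV = 1e-8, rankL = 1L, rankD = 4L,
                 ctrlX = 90L, ctrlY = 90L, ctrlT = 40L),
    test3 = list(lambdaS = 1, lambdaTV = 1e-7, rankL = 1L, rankD = 1L,
                 ctrlX = 80L, ctrlY = 80L, ctrlT = NA_integer_),
    test4 = list(lambdaS = 5, lambdaTV = 1e-8, rankL = 1L, rankD = 3L,
                 ctrlX = 64L, ctrlY = 64L, ctrlT = 150L))
  over <- list(...)
  do.call(ReconConfig, c(over, base[setdiff(names(base), names(over))]))
}

#' Phantom presets
#'
#' Acquisition presets of the bundled phantom: `test1` is the Cartesian
#' perfusion setup (12 pseudo-random readouts/frame), `test3` and `test4`
#' its golden-angle radial variants with 10 and 20 spokes/frame.
#'
#' @param name preset name.
#' @param ... overrides passed to [PhantomConfig()].
#' @return a [PhantomConfig-class].
#' @export
phantomPreset <- function(name = c("test1", "test3", "test4"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    test1 = list(),
    test3 = list(scheme = "radial_golden_angle", readouts = 10L),
    test4 = list(scheme = "radial_golden_angle", readouts = 20L))
  over <- list(...)
  do.call(PhantomConfig, c(over, base[setdiff(names(base), names(over))]))
}

#' Load a reconstruction configuration from a YAML file
#'
#' A flat key/value YAML file whose keys are [ReconConfig-class] slot names;
#' an optional `preset` key (`test1` ... `test4`) supplies base values that
#' individual keys may override. Absent keys take the package defaults; all
#' invariants are validated.
#'
#' @param path YAML file path.
#' @return a [ReconConfig-class].
#' @export
loadConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  if (is.null(lst)) lst <- list()
  if (!is.null(lst$preset)) {
    preset <- lst$preset
    lst$preset <- NULL
    return(do.call(reconPreset, c(list(name = preset), lst)))
  }
  do.call(ReconConfig, lst)
}

#' Evaluations that require external data
#'
#' The full-scale validation experiments depend on inputs that cannot be
#' redistributed with the package: the licensed XCAT/MRXCAT digital phantom
#' (full 600-frame perfusion simulation), the public OCMR free-running cine
#' raw data, and patient perfusion raw data. This function documents those
#' evaluations and reports whether user-supplied input files are available;
#' no values are produced unless the data are provided.
#'
#' @param paths optional named character vector of user-supplied file paths
#'   (names: `xcat`, `ocmr`, `perfusion`).
#' @return data.frame with columns `target`, `requires`, `available`.
#' @export
externalTargets <- function(paths = character()) {
  req <- c(xcat = "XCAT/MRXCAT licensed phantom (600-frame perfusion run)",
           ocmr = "OCMR free-running cine raw k-space",
           perfusion = "patient radial perfusion raw k-space")
  avail <- vapply(names(req), function(nm)
    nm %in% names(paths) && file.exists(paths[[nm]]), logical(1))
  data.frame(
    target = c("SSIM/DICE/EPE on the full-scale perfusion simulation",
               "Tenengrad sharpness comparison on free-running cine",
               "motion/contrast disentanglement on patient perfusion"),
    requires = unname(req),
    available = unname(avail),
    stringsAsFactors = FALSE)
}

#' Export a cine series to NIfTI
#'
#' Magnitude export for viewing (requires the RNifti package).
#'
#' @param cine a [CineSeries-class].
#' @param path output file (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
exportCineNifti <- function(cine, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  g <- cine@grid
  arr <- array(Mod(cine@H), c(g@nx, g@ny, 1L, ncol(cine@H)))
  img <- RNifti::asNifti(arr, pixdim = c(g@dx, g@dy, 1, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}
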