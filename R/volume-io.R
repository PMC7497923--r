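# Volume reading/writing (NIfTI via RNifti, MetaImage natively) and the
# preprocessing chain: resampling, air-removal crop, robust intensity
# normalization to (-1, 1).

.guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lp)) return("metaimage")
  stop("cannot guess volume format from path: ", path)
}

.check_finite <- function(data, path = NULL) {
  if (any(!is.finite(data)))
    stop("volume contains NaN/Inf intensities",
         if (!is.null(path)) paste0(": ", path) else "")
  invisible(NULL)
}

# Internal: write a plain array as NIfTI with geometry. The affine is a
# positive diagonal of the spacing plus the origin translation (volumes
# are axis-aligned by convention).
.write_nifti_array <- function(data, spacing, origin, path) {
  attr(data, "pixdim") <- spacing
  img <- RNifti::asNifti(data, datatype = "double")
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(NULL)
}

.read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  pd <- RNifti::pixdim(img)
  aff <- RNifti::xform(img)
  origin <- as.numeric(aff[1:3, 4])
  data <- as.array(img)
  attributes(data) <- list(dim = dim(img))
  list(data = data, spacing = abs(as.numeric(pd[1:3])), origin = origin)
}

.met_types <- list(
  MET_DOUBLE = list(what = "double", size = 8L, mode = "double"),
  MET_FLOAT  = list(what = "double", size = 4L, mode = "double"),
  MET_SHORT  = list(what = "integer", size = 2L, mode = "integer"),
  MET_USHORT = list(what = "integer", size = 2L, mode = "integer"),
  MET_UCHAR  = list(what = "integer", size = 1L, mode = "integer"),
  MET_INT    = list(what = "integer", size = 4L, mode = "integer"))

.read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header: ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (is.null(hdr$DimSize)) stop("MetaImage header missing DimSize: ", path)
  if (is.null(hdr$ElementSpacing))
    stop("MetaImage header missing ElementSpacing metadata: ", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- .met_types[[hdr$ElementType]]
  if (is.null(type)) stop("unsupported MetaImage ElementType: ", hdr$ElementType)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported: ", path)
  n <- prod(dims)
  if (hdr$ElementDataFile == "LOCAL") {
    raw <- readBin(con, type$what, n = n, size = type$size,
                   endian = "little",
                   signed = !(hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT")))
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("MetaImage raw file not found: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, type$what, n = n, size = type$size,
                   endian = "little",
                   signed = !(hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT")))
  }
  if (length(raw) != n) stop("truncated MetaImage data block: ", path)
  list(data = array(as.double(raw), dims), spacing = spacing, origin = origin)
}

.write_metaimage <- function(data, spacing, origin, path) {
  local_data <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_data) "LOCAL" else
    sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(data), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.double(data), rcon, size = 8L, endian = "little")
  }
  invisible(NULL)
}

#' Load a volume from NIfTI or MetaImage
#'
#' Reads intensities unmodified together with voxel spacing and origin
#' from the file header. NaN/Inf intensities are rejected with an error
#' rather than propagated.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @param format `"nifti"` or `"metaimage"`; guessed from the extension
#'   when `NULL`.
#' @param modality modality tag for the returned volume.
#' @return A [Volume-class].
#' @export
loadVolume <- function(path, format = NULL, modality = "SYNTH_A") {
  if (!file.exists(path)) stop("cannot read volume, file not found: ", path)
  format <- match.arg(format %||% .guess_format(path), c("nifti", "metaimage"))
  raw <- if (format == "nifti") .read_nifti_array(path) else
    .read_metaimage(path)
  if (any(!is.finite(raw$spacing)) || any(raw$spacing <= 0))
    stop("missing or invalid spacing metadata in: ", path)
  .check_finite(raw$data, path)
  Volume(raw$data, spacing = raw$spacing, origin = raw$origin,
         modality = modality)
}

#' Save a volume to NIfTI or MetaImage
#'
#' The emitted file round-trips through [loadVolume()] bit-exactly
#' (double-precision storage).
#'
#' @param v a [Volume-class].
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @param format `"nifti"` or `"metaimage"`; guessed from the extension
#'   when `NULL`.
#' @return Invisibly, `path`.
#' @export
saveVolume <- function(v, path, format = NULL) {
  stopifnot(is(v, "Volume"))
  .check_finite(v@data)
  format <- match.arg(format %||% .guess_format(path), c("nifti", "metaimage"))
  if (format == "nifti")
    .write_nifti_array(v@data, v@spacing, v@origin, path)
  else
    .write_metaimage(v@data, v@spacing, v@origin, path)
  invisible(path)
}

#' Resample a volume to a target spacing
#'
#' Trilinear interpolation onto a new grid whose physical extent matches
#' the input to within one output voxel. Resampling to the volume's own
#' spacing reproduces it exactly.
#'
#' @param v a [Volume-class].
#' @param targetSpacing numeric(3), mm per voxel, strictly positive.
#' @return A resampled [Volume-class].
#' @export
resampleVolume <- function(v, targetSpacing) {
  stopifnot(is(v, "Volume"))
  targetSpacing <- as.numeric(targetSpacing)
  if (length(targetSpacing) != 3L || any(!is.finite(targetSpacing)) ||
      any(targetSpacing <= 0))
    stop("targetSpacing must be 3 strictly positive numbers")
  d <- dim(v@data)
  ratio <- v@spacing / targetSpacing
  nd <- pmax(1L, as.integer(round(d * ratio)))
  ax <- lapply(1:3, function(a)
    (seq_len(nd[a]) - 1) / ratio[a])
  coords <- cbind(
    rep(ax[[1]], times = nd[2] * nd[3]),
    rep(rep(ax[[2]], each = nd[1]), times = nd[3]),
    rep(ax[[3]], each = nd[1] * nd[2]))
  vals <- cpp_sample_trilinear(v@data, coords)
  Volume(array(vals, nd), spacing = targetSpacing, origin = v@origin,
         modality = v@modality)
}

#' Crop or pad a volume to a fixed grid size
#'
#' The cropping window is centered either on the grid center or on the
#' centroid of foreground voxels (intensity above the `fgQuantile`
#' threshold, emulating removal of redundant air). Where the window
#' extends beyond the input, the air value (minimum intensity) is used
#' as padding.
#'
#' @param v a [Volume-class].
#' @param targetSize integer(3) output grid size.
#' @param centerMode `"grid_center"` or `"foreground_centroid"`.
#' @param fgQuantile quantile defining the foreground threshold
#'   (default 0.05).
#' @return A [Volume-class] with dimensions `targetSize`.
#' @export
cropOrPad <- function(v, targetSize,
                      centerMode = c("grid_center", "foreground_centroid"),
                      fgQuantile = 0.05) {
  stopifnot(is(v, "Volume"))
  centerMode <- match.arg(centerMode)
  targetSize <- as.integer(targetSize)
  if (length(targetSize) != 3L || any(targetSize < 1L))
    stop("targetSize must be 3 positive integers")
  d <- dim(v@data)
  center <- (d - 1) / 2
  if (centerMode == "foreground_centroid") {
    thr <- quantile(v@data, fgQuantile, names = FALSE)
    fg <- which(v@data > thr, arr.ind = TRUE)
    if (nrow(fg)) center <- colMeans(fg) - 1  # 0-based
  }
  start <- round(center - (targetSize - 1) / 2)
  air <- min(v@data)
  out <- array(air, targetSize)
  src <- lapply(1:3, function(a) start[a] + seq_len(targetSize[a]) - 1)
  valid <- lapply(1:3, function(a) src[[a]] >= 0 & src[[a]] < d[a])
  if (all(vapply(valid, any, TRUE))) {
    out[valid[[1]], valid[[2]], valid[[3]]] <-
      v@data[src[[1]][valid[[1]]] + 1, src[[2]][valid[[2]]] + 1,
             src[[3]][valid[[3]]] + 1]
  }
  origin <- v@origin + start * v@spacing
  Volume(out, spacing = v@spacing, origin = origin, modality = v@modality)
}

#' Robust intensity normalization to (-1, 1)
#'
#' Maps the `lowerPct` percentile to -1 and the `upperPct` percentile to
#' +1, linearly in between, clamping outside; a percentile-based
#' standardization ahead of training. Constant volumes return all zeros
#' with a warning.
#'
#' @param v a [Volume-class].
#' @param lowerPct,upperPct percentiles in `[0, 1]`, `lowerPct < upperPct`.
#' @return A [Volume-class] with intensities in `[-1, 1]`.
#' @export
normalizeIntensity <- function(v, lowerPct = 0.01, upperPct = 0.99) {
  stopifnot(is(v, "Volume"))
  if (!(lowerPct >= 0 && lowerPct < upperPct && upperPct <= 1))
    stop("require 0 <= lowerPct < upperPct <= 1")
  q <- quantile(v@data, c(lowerPct, upperPct), names = FALSE)
  rng <- q[2] - q[1]
  if (rng <= 0) {
    warning("constant intensity volume: normalization returns all zeros")
    return(Volume(array(0, dim(v@data)), spacing = v@spacing,
                  origin = v@origin, modality = v@modality))
  }
  y <- 2 * (v@data - q[1]) / rng - 1
  y[y < -1] <- -1
  y[y > 1] <- 1
  Volume(y, spacing = v@spacing, origin = v@origin, modality = v@modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
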