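#' @import methods
#' @importFrom stats quantile rnorm sd setNames
#' @importFrom utils read.csv write.csv
#' @useDynLib CycleMIND, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.modalities <- c("CT", "MR", "SYNTH_A", "SYNTH_B")

#' Volume: a 3D scalar image with voxel geometry
#'
#' The unit of data moved through the registration pipeline: a dense 3D
#' scalar grid together with its voxel spacing (mm per voxel along each
#' axis), physical origin (mm) and a modality tag. Volumes are assumed
#' axis-aligned: voxel index `(i, j, k)` (0-based) sits at physical
#' position `origin + c(i, j, k) * spacing`.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), mm per voxel, strictly positive.
#' @slot origin numeric(3), physical position of voxel (0,0,0) in mm.
#' @slot modality one of `"CT"`, `"MR"`, `"SYNTH_A"`, `"SYNTH_B"`.
#' @exportClass Volume
setClass("Volume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 modality = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), modality = "CT"))

setValidity("Volume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (any(dim(object@data) < 1L))
    msg <- c(msg, "data dimensions must each be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (length(object@modality) != 1L || !(object@modality %in% .modalities))
    msg <- c(msg, paste("modality must be one of:",
                        paste(.modalities, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Volume
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) physical origin in mm.
#' @param modality modality tag.
#' @return A [Volume-class] object.
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   modality = "SYNTH_A") {
  if (is.null(dim(data))) stop("data must be a 3D array")
  storage.mode(data) <- "double"
  new("Volume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality)
}

#' ROIMask: integer label image aligned with a Volume
#'
#' Label 0 is background; positive labels index regions of interest
#' (e.g. bladder, rectum). The grid must match its companion Volume.
#'
#' @slot labels 3D integer array.
#' @slot labelNames named character vector mapping label value (as a
#'   name) to a region name.
#' @slot spacing numeric(3) mm, inherited from the companion Volume.
#' @exportClass ROIMask
setClass("ROIMask",
  representation(labels = "array", labelNames = "character",
                 spacing = "numeric"),
  prototype(spacing = c(1, 1, 1), labelNames = character()))

setValidity("ROIMask", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (any(object@labels < 0, na.rm = TRUE))
    msg <- c(msg, "labels must be non-negative (0 = background)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' Construct an ROIMask
#'
#' @param labels 3D integer array (0 = background).
#' @param labelNames named character vector, names are label values.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return An [ROIMask-class] object.
#' @export
ROIMask <- function(labels, labelNames = character(), spacing = c(1, 1, 1)) {
  storage.mode(labels) <- "integer"
  new("ROIMask", labels = labels, labelNames = labelNames,
      spacing = as.numeric(spacing))
}

#' DeformationField: dense per-voxel displacement
#'
#' A 4D array `(nx, ny, nz, 3)` of displacement vectors in voxel units,
#' following the resampling (pull-back) convention: warping a moving
#' volume `v` by field `f` produces `out(x) = v(x + f(x))`, so the zero
#' field is the identity transform.
#'
#' @slot displacements 4D numeric array, last dimension of extent 3.
#' @slot spacing numeric(3) mm, used to convert displacements to mm.
#' @exportClass DeformationField
setClass("DeformationField",
  representation(displacements = "array", spacing = "numeric"),
  prototype(spacing = c(1, 1, 1)))

setValidity("DeformationField", function(object) {
  msg <- character()
  d <- dim(object@displacements)
  if (length(d) != 4L || d[4] != 3L)
    msg <- c(msg, "displacements must be a 4D array with 3 components")
  if (any(!is.finite(object@displacements)))
    msg <- c(msg, "displacements must all be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' Construct a DeformationField
#'
#' @param displacements 4D numeric array `(nx, ny, nz, 3)`, voxel units.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return A [DeformationField-class] object.
#' @export
DeformationField <- function(displacements, spacing = c(1, 1, 1)) {
  storage.mode(displacements) <- "double"
  new("DeformationField", displacements = displacements,
      spacing = as.numeric(spacing))
}

#' LandmarkSet: named points in physical coordinates
#'
#' @slot points numeric matrix, one row per landmark, columns x/y/z mm.
#' @slot labels character vector of landmark names.
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(points = "matrix", labels = "character"))

setValidity("LandmarkSet", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L)
    msg <- c(msg, "points must have 3 columns (x, y, z in mm)")
  if (any(!is.finite(object@points)))
    msg <- c(msg, "landmark coordinates must be finite")
  if (length(object@labels) != nrow(object@points))
    msg <- c(msg, "labels must match the number of points")
  if (length(msg)) msg else TRUE
})

#' Construct a LandmarkSet
#'
#' @param points numeric matrix (n x 3) of physical coordinates in mm.
#' @param labels character vector of landmark names.
#' @return A [LandmarkSet-class] object.
#' @export
LandmarkSet <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (is.null(labels)) labels <- paste0("pt", seq_len(nrow(points)))
  new("LandmarkSet", points = points, labels = as.character(labels))
}

#' MindConfig: parameters of the neighborhood descriptor
#'
#' Configures the modality-independent neighborhood descriptor: the
#' patch over which intensity patches are compared, the search region of
#' offsets at which responses are computed, the neighborhood used for
#' the local variance estimate, and the variance floor. By default
#' patches and regions are in-plane (2D), matching thick-slice
#' acquisitions; a 3D mode uses cubic patches and regions.
#'
#' @slot patchSize odd integer, patch edge length (default 5).
#' @slot regionSize odd integer, search region edge length (default 7).
#' @slot searchRegion integer matrix of offsets (rows), zero excluded.
#' @slot varNeighborhood integer matrix of offsets used for the variance
#'   estimate (default: 4-connected in-plane).
#' @slot epsilon non-negative numeric; absolute variance floor. 0 means
#'   automatic: `epsilonScale * (intensity range)^2` per image.
#' @slot epsilonScale positive numeric, scale of the automatic floor.
#' @slot mode2d logical; in-plane (TRUE) or cubic (FALSE) geometry.
#' @slot smoothSigma non-negative numeric; in-plane Gaussian prefilter
#'   (voxels) applied to images before descriptor extraction. 0 disables.
#' @exportClass MindConfig
setClass("MindConfig",
  representation(patchSize = "integer", regionSize = "integer",
                 searchRegion = "matrix", varNeighborhood = "matrix",
                 epsilon = "numeric", epsilonScale = "numeric",
                 mode2d = "logical", smoothSigma = "numeric"))

setValidity("MindConfig", function(object) {
  msg <- character()
  if (object@patchSize < 1L || object@patchSize %% 2L == 0L)
    msg <- c(msg, "patchSize must be odd and >= 1")
  if (object@regionSize < 1L || object@regionSize %% 2L == 0L)
    msg <- c(msg, "regionSize must be odd and >= 1")
  if (nrow(object@searchRegion) &&
      any(rowSums(abs(object@searchRegion)) == 0))
    msg <- c(msg, "the zero offset must be excluded from the search region")
  if (object@epsilon < 0)
    msg <- c(msg, "epsilon must be >= 0")
  if (object@epsilonScale <= 0)
    msg <- c(msg, "epsilonScale must be > 0")
  if (object@smoothSigma < 0)
    msg <- c(msg, "smoothSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' NetworkConfig: architecture of the displacement-regression FCN
#'
#' @slot inSize integer(3) input grid size; in-plane sizes must be
#'   divisible by `2^nScales`.
#' @slot baseChannels integer, channels after the first convolution;
#'   widths double at each scale.
#' @slot nResBlocks integer, residual blocks at the coarsest scale.
#' @slot nScales integer, number of stride-2 down/up levels.
#' @slot finalZeroInit logical; start from the identity transform.
#' @slot maxDisplacement numeric, voxels; the output field is
#'   `maxDisplacement * tanh(raw)`.
#' @slot strideZ integer, through-plane stride at each scale (default 1,
#'   keeping thin stacks unreduced).
#' @slot norm `"instance"` or `"none"`, normalization in residual blocks.
#' @slot fieldSmoothSigma non-negative numeric; in-plane Gaussian
#'   smoothing of the output field inside the network (a fixed linear
#'   layer before the scaled tanh). Keeps the regressed field free of
#'   upsampling blockiness; 0 disables.
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(inSize = "integer", baseChannels = "integer",
                 nResBlocks = "integer", nScales = "integer",
                 finalZeroInit = "logical", maxDisplacement = "numeric",
                 strideZ = "integer", norm = "character",
                 fieldSmoothSigma = "numeric"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (length(object@inSize) != 3L || any(object@inSize < 1L))
    msg <- c(msg, "inSize must be 3 positive integers")
  f <- 2L^object@nScales
  if (any(object@inSize[1:2] %% f != 0L))
    msg <- c(msg, sprintf("in-plane sizes must be divisible by 2^nScales (%d)", f))
  if (object@strideZ == 2L && object@inSize[3] %% (object@strideZ^object@nScales) != 0L)
    msg <- c(msg, "through-plane size must be divisible by strideZ^nScales")
  if (object@nResBlocks < 1L)
    msg <- c(msg, "nResBlocks must be >= 1")
  if (object@maxDisplacement <= 0)
    msg <- c(msg, "maxDisplacement must be > 0")
  if (!object@norm %in% c("instance", "none"))
    msg <- c(msg, "norm must be 'instance' or 'none'")
  if (length(msg)) msg else TRUE
})

#' RegistrationNetwork: an FCN regressing a displacement field
#'
#' Holds the architecture configuration and the trainable parameter
#' arrays of one registration network G mapping a two-channel
#' (moving, fixed) volume pair to a dense displacement field of the same
#' grid size.
#'
#' @slot config a [NetworkConfig-class].
#' @slot params named list of numeric parameter arrays.
#' @exportClass RegistrationNetwork
setClass("RegistrationNetwork",
  representation(config = "NetworkConfig", params = "list"))

#' LossWeights: coefficients of the three training loss terms
#'
#' @slot lambdaCont weight of the MIND content loss (default 5).
#' @slot lambdaReg weight of the field regularization loss (default 1).
#' @slot lambdaCyc weight of the cycle-reconstruction loss (default 1).
#' @exportClass LossWeights
setClass("LossWeights",
  representation(lambdaCont = "numeric", lambdaReg = "numeric",
                 lambdaCyc = "numeric"))

setValidity("LossWeights", function(object) {
  if (any(c(object@lambdaCont, object@lambdaReg, object@lambdaCyc) < 0))
    "loss weights must be >= 0" else TRUE
})

#' Construct LossWeights
#'
#' @param lambdaCont,lambdaReg,lambdaCyc non-negative weights of the
#'   content, regularization and cycle losses.
#' @return A [LossWeights-class] object.
#' @export
LossWeights <- function(lambdaCont = 5, lambdaReg = 1, lambdaCyc = 1) {
  new("LossWeights", lambdaCont = lambdaCont, lambdaReg = lambdaReg,
      lambdaCyc = lambdaCyc)
}

#' TrainState: the pair of networks plus optimization state
#'
#' @slot netAB network deforming volume A toward volume B.
#' @slot netBA network deforming volume B toward volume A.
#' @slot optState opaque optimizer state (Adam moments).
#' @slot epoch integer, epochs completed.
#' @slot lossHistory data.frame of per-step loss terms.
#' @exportClass TrainState
setClass("TrainState",
  representation(netAB = "RegistrationNetwork", netBA = "RegistrationNetwork",
                 optState = "list", epoch = "integer",
                 lossHistory = "data.frame"))

setValidity("TrainState", function(object) {
  h <- object@lossHistory
  if (nrow(h) && any(!is.finite(as.matrix(h[vapply(h, is.numeric, TRUE)]))))
    "lossHistory contains non-finite terms" else TRUE
})

#' PhantomConfig: parameters of the synthetic multimodal phantom
#'
#' The generator emulates rigidly pre-aligned multimodal pairs: a shared
#' anatomy rendered through two different (non-monotone across tissue
#' classes) intensity maps, a smooth random residual deformation between
#' the pair, per-modality noise, organ masks and bone-shell landmarks.
#'
#' @slot size integer(3) grid size (default 32 x 32 x 8).
#' @slot spacing numeric(3) mm (default 1 x 1 x 5, anisotropic).
#' @slot nOrgans integer, 2 = bladder-like ellipsoid + rectum-like tube.
#' @slot amplitude numeric, maximum in-plane displacement in voxels.
#' @slot smoothness numeric, Gaussian scale of the random field, voxels.
#' @slot noiseSd numeric, additive Gaussian noise SD (intensity units of
#'   the unit-range anatomy rendering).
#' @slot seed integer random seed.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(size = "integer", spacing = "numeric", nOrgans = "integer",
                 amplitude = "numeric", smoothness = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@smoothness <= 0) msg <- c(msg, "smoothness must be > 0")
  if (object@nOrgans < 1L || object@nOrgans > 2L)
    msg <- c(msg, "nOrgans must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomConfig
#'
#' @param size integer(3) grid size.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param nOrgans number of organs (1 or 2).
#' @param amplitude maximum in-plane displacement, voxels.
#' @param smoothness Gaussian scale of the deformation, voxels.
#' @param noiseSd additive noise standard deviation.
#' @param seed integer random seed.
#' @return A [PhantomConfig-class] object.
#' @export
PhantomConfig <- function(size = c(32L, 32L, 8L), spacing = c(1, 1, 5),
                          nOrgans = 2L, amplitude = 3, smoothness = 8,
                          noiseSd = 0.02, seed = 1L) {
  new("PhantomConfig", size = as.integer(size), spacing = as.numeric(spacing),
      nOrgans = as.integer(nOrgans), amplitude = amplitude,
      smoothness = smoothness, noiseSd = noiseSd, seed = as.integer(seed))
}

#' PhantomCase: one synthetic multimodal pair with ground truth
#'
#' `gtField` is defined on the grid of `volA` and registers B to A:
#' warping `volB` (or `maskB`) by `gtField` brings it into alignment
#' with `volA` (`maskA`).
#'
#' @slot volA pseudo-CT [Volume-class] (fixed).
#' @slot volB pseudo-MR [Volume-class] (moving; deformed anatomy).
#' @slot maskA,maskB organ [ROIMask-class] objects for each volume.
#' @slot gtField ground-truth [DeformationField-class] (B into A).
#' @slot landmarksA,landmarksB paired [LandmarkSet-class] objects.
#' @slot config the generating [PhantomConfig-class].
#' @exportClass PhantomCase
setClass("PhantomCase",
  representation(volA = "Volume", volB = "Volume", maskA = "ROIMask",
                 maskB = "ROIMask", gtField = "DeformationField",
                 landmarksA = "LandmarkSet", landmarksB = "LandmarkSet",
                 config = "PhantomConfig"))
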