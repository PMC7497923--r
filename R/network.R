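# The displacement-regression FCN: a two-channel (moving, fixed) volume
# pair goes through stride-2 downsampling convolutions, residual blocks
# at the coarsest scale, and resize-convolution upsampling back to the
# input grid, ending in a 1x1x1 convolution to 3 displacement channels
# passed through a scaled tanh.

#' Configure the registration network
#'
#' @param inSize integer(3) input grid size; in-plane sizes must be
#'   divisible by `2^nScales`.
#' @param baseChannels channels after the first convolution; widths
#'   double at each coarser scale (default 32).
#' @param nResBlocks residual blocks at the coarsest scale (default 9).
#' @param nScales stride-2 down/up levels (default 3).
#' @param finalZeroInit start the last layer at zero so the initial
#'   output is the identity transform (default TRUE).
#' @param maxDisplacement bound on output displacements in voxels; the
#'   field is `maxDisplacement * tanh(raw)` (default 10).
#' @param strideZ through-plane stride per scale; 1 (default) keeps thin
#'   slice stacks unreduced.
#' @param norm normalization inside residual blocks: `"instance"`
#'   (default) or `"none"`.
#' @param fieldSmoothSigma in-plane Gaussian smoothing of the raw field
#'   inside the network, in voxels (default 1; 0 disables). Displacement
#'   fields are spatially smooth by nature; a fixed smoothing layer
#'   removes resize-convolution blockiness from the regressed field so
#'   the smoothness penalty acts on genuine roughness only.
#' @return A [NetworkConfig-class].
#' @export
networkConfig <- function(inSize = c(200L, 200L, 24L), baseChannels = 32L,
                          nResBlocks = 9L, nScales = 3L,
                          finalZeroInit = TRUE, maxDisplacement = 10,
                          strideZ = 1L, norm = "instance",
                          fieldSmoothSigma = 1) {
  new("NetworkConfig", inSize = as.integer(inSize),
      baseChannels = as.integer(baseChannels),
      nResBlocks = as.integer(nResBlocks), nScales = as.integer(nScales),
      finalZeroInit = finalZeroInit, maxDisplacement = maxDisplacement,
      strideZ = as.integer(strideZ), norm = norm,
      fieldSmoothSigma = as.numeric(fieldSmoothSigma))
}

.net_channels <- function(cfg) {
  as.integer(cfg@baseChannels * 2^(seq_len(cfg@nScales) - 1))
}

.he_init <- function(kdim, cin, cout) {
  sd <- sqrt(2 / (prod(kdim) * cin))
  array(rnorm(prod(kdim) * cin * cout, sd = sd), c(kdim, cin, cout))
}

#' Build a registration network
#'
#' Parameter initialization is deterministic given `seed` (He-normal
#' convolution weights, zero biases; the final layer starts at zero when
#' `finalZeroInit` so the initial predicted field is identically zero).
#'
#' @param cfg a [NetworkConfig-class].
#' @param seed integer random seed for the initialization.
#' @return A [RegistrationNetwork-class].
#' @export
buildNetwork <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "NetworkConfig"))
  validObject(cfg)
  set.seed(seed)
  chans <- .net_channels(cfg)
  k3 <- c(3L, 3L, 3L)
  params <- list()
  cins <- c(2L, chans[-cfg@nScales])
  for (i in seq_len(cfg@nScales)) {
    params[[paste0("down", i, ".w")]] <- .he_init(k3, cins[i], chans[i])
    params[[paste0("down", i, ".b")]] <- numeric(chans[i])
  }
  cc <- chans[cfg@nScales]
  for (i in seq_len(cfg@nResBlocks)) {
    params[[paste0("res", i, ".w1")]] <- .he_init(k3, cc, cc)
    params[[paste0("res", i, ".b1")]] <- numeric(cc)
    params[[paste0("res", i, ".w2")]] <- .he_init(k3, cc, cc)
    params[[paste0("res", i, ".b2")]] <- numeric(cc)
  }
  upin <- rev(chans)
  upout <- c(rev(chans)[-1], chans[1])
  for (j in seq_len(cfg@nScales)) {
    params[[paste0("up", j, ".w")]] <- .he_init(k3, upin[j], upout[j])
    params[[paste0("up", j, ".b")]] <- numeric(upout[j])
  }
  if (cfg@finalZeroInit) {
    params[["final.w"]] <- array(0, c(1L, 1L, 1L, chans[1], 3L))
    params[["final.b"]] <- numeric(3L)
  } else {
    # small random head keeps the scaled-tanh output off saturation
    params[["final.w"]] <- 0.1 * .he_init(c(1L, 1L, 1L), chans[1], 3L)
    params[["final.b"]] <- numeric(3L)
  }
  new("RegistrationNetwork", config = cfg, params = params)
}

#' Network accessors
#'
#' @param net a [RegistrationNetwork-class].
#' @return `netConfig`: the [NetworkConfig-class]; `netParams`: the
#'   named list of parameter arrays; `networkParameterCount`: total
#'   number of trainable scalars.
#' @export
netConfig <- function(net) net@config

#' @rdname netConfig
#' @export
netParams <- function(net) net@params

#' @rdname netConfig
#' @export
networkParameterCount <- function(net)
  sum(vapply(net@params, length, 1L))

# Build the forward graph from parameter nodes and input volume nodes.
# Returns the field node (nx, ny, nz, 3).
.net_forward <- function(pn, cfg, mov, fix) {
  s <- c(2L, 2L, cfg@strideZ)
  p1 <- c(1L, 1L, 1L)
  x <- ag_concat2(mov, fix)
  for (i in seq_len(cfg@nScales))
    x <- ag_relu(ag_conv3d(x, pn[[paste0("down", i, ".w")]],
                           pn[[paste0("down", i, ".b")]], s, p1))
  for (i in seq_len(cfg@nResBlocks)) {
    y <- ag_conv3d(x, pn[[paste0("res", i, ".w1")]],
                   pn[[paste0("res", i, ".b1")]], p1, p1)
    if (cfg@norm == "instance") y <- ag_instnorm(y)
    y <- ag_relu(y)
    y <- ag_conv3d(y, pn[[paste0("res", i, ".w2")]],
                   pn[[paste0("res", i, ".b2")]], p1, p1)
    if (cfg@norm == "instance") y <- ag_instnorm(y)
    x <- ag_add(x, y)
  }
  for (j in seq_len(cfg@nScales)) {
    x <- ag_upsample(x, s)
    x <- ag_relu(ag_conv3d(x, pn[[paste0("up", j, ".w")]],
                           pn[[paste0("up", j, ".b")]], p1, p1))
  }
  raw <- ag_conv3d(x, pn[["final.w"]], pn[["final.b"]], p1, c(0L, 0L, 0L))
  if (cfg@fieldSmoothSigma > 0) {
    comps <- lapply(1:3, function(c)
      .ag_inplane_smooth(ag_slice4(raw, c), cfg@fieldSmoothSigma))
    raw <- ag_stack4(comps)
  }
  ag_tanh_scale(raw, cfg@maxDisplacement)
}

.check_net_input <- function(cfg, v, what) {
  if (!identical(dim(v@data), as.integer(cfg@inSize)))
    stop(sprintf("%s volume size (%s) does not match network input size (%s)",
                 what, paste(dim(v@data), collapse = "x"),
                 paste(cfg@inSize, collapse = "x")))
  invisible(NULL)
}

#' Predict a displacement field for a volume pair
#'
#' Runs the network in inference mode on a (moving, fixed) pair whose
#' grids match the configured input size; intensities are expected to be
#' normalized to `[-1, 1]` (see [normalizeIntensity()]).
#'
#' @param net a [RegistrationNetwork-class].
#' @param moving,fixed [Volume-class] objects of the configured size.
#' @return A [DeformationField-class] on the same grid.
#' @export
predictField <- function(net, moving, fixed) {
  stopifnot(is(net, "RegistrationNetwork"))
  .check_net_input(net@config, moving, "moving")
  .check_net_input(net@config, fixed, "fixed")
  pn <- lapply(net@params, ag_const)
  fld <- .net_forward(pn, net@config, ag_const(moving@data),
                      ag_const(fixed@data))
  DeformationField(ag_value(fld), spacing = moving@spacing)
}

#' A stub network emitting a constant displacement field
#'
#' Builds a network whose output is the given constant displacement at
#' every voxel regardless of input (all feature weights zero, the final
#' bias set to `atanh(t / maxDisplacement)`). Useful for composing
#' hand-checkable transforms in tests and demonstrations.
#'
#' @param cfg a [NetworkConfig-class]; `maxDisplacement` must exceed
#'   `max(abs(translation))`.
#' @param translation numeric(3) constant displacement in voxels.
#' @return A [RegistrationNetwork-class].
#' @export
constantFieldNetwork <- function(cfg, translation) {
  stopifnot(length(translation) == 3L,
            all(abs(translation) < cfg@maxDisplacement))
  net <- buildNetwork(cfg, seed = 0L)
  for (nm in names(net@params)) net@params[[nm]][] <- 0
  net@params[["final.b"]] <- atanh(translation / cfg@maxDisplacement)
  net
}

#' Save / load a network checkpoint
#'
#' One file per network, configuration embedded, written with R's
#' native serialization.
#'
#' @param net a [RegistrationNetwork-class].
#' @param path checkpoint file path.
#' @return `loadNetworkCheckpoint` returns the restored network.
#' @export
saveNetworkCheckpoint <- function(net, path) {
  stopifnot(is(net, "RegistrationNetwork"))
  saveRDS(list(config = net@config, params = net@params), path)
  invisible(path)
}

#' @rdname saveNetworkCheckpoint
#' @export
loadNetworkCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  new("RegistrationNetwork", config = obj$config, params = obj$params)
}
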