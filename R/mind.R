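# Modality-independent neighborhood descriptor (MIND) and the content
# loss built on it.
#
# Per voxel x and search offset r, the descriptor is
#   MIND(I, x, r) = exp(-D(I, x, r) / V(I, x)) / n(x),
# where D is the summed squared difference between the image patch at x
# and the patch at x + r, V is the mean of D over a small neighborhood
# of offsets (a local variance estimate, floored at epsilon), and n(x)
# normalizes the per-voxel maximum over the search region to 1.
#
# Boundary convention: patch voxel positions are clamped to the grid,
# and the offset read is clamped again, i.e.
#   D(x, r) = sum_p ( I(c(x+p)) - I(c(c(x+p)+r)) )^2,   c = clamp.
# This makes the dense evaluation a shifted-difference plus box-sum,
# with no per-voxel loops.

#' Configure the neighborhood descriptor
#'
#' @param patchSize odd integer edge length of the comparison patch
#'   (default 5).
#' @param regionSize odd integer edge length of the search region; the
#'   zero offset is excluded (default 7).
#' @param mode2d logical; if TRUE (default) patches, region and variance
#'   neighborhood are in-plane, matching thick-slice volumes. If FALSE,
#'   cubic patches/region and a 6-connected variance neighborhood.
#' @param epsilon absolute variance floor; 0 (default) selects
#'   `epsilonScale * (intensity range)^2` per image.
#' @param epsilonScale scale of the automatic variance floor.
#' @param smoothSigma in-plane Gaussian prefilter in voxels applied to
#'   both images before descriptor extraction (0 = none, the pure
#'   definition). A mild prefilter (about 1 voxel) suppresses the
#'   noise-driven descriptor floor on weakly textured regions and is
#'   used in the training configuration.
#' @return A [MindConfig-class].
#' @export
mindConfig <- function(patchSize = 5L, regionSize = 7L, mode2d = TRUE,
                       epsilon = 0, epsilonScale = 1e-6,
                       smoothSigma = 0) {
  patchSize <- as.integer(patchSize)
  regionSize <- as.integer(regionSize)
  h <- (regionSize - 1L) %/% 2L
  if (mode2d) {
    g <- expand.grid(dx = -h:h, dy = -h:h, dz = 0L)
    varn <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                  c(0L, -1L, 0L))
  } else {
    g <- expand.grid(dx = -h:h, dy = -h:h, dz = -h:h)
    varn <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                  c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  }
  search <- as.matrix(g[rowSums(abs(g)) != 0L, , drop = FALSE])
  dimnames(search) <- NULL
  storage.mode(search) <- "integer"
  storage.mode(varn) <- "integer"
  new("MindConfig", patchSize = patchSize, regionSize = regionSize,
      searchRegion = search, varNeighborhood = varn,
      epsilon = as.numeric(epsilon), epsilonScale = epsilonScale,
      mode2d = mode2d, smoothSigma = as.numeric(smoothSigma))
}

# Differentiable separable in-plane Gaussian smoothing (a weighted sum
# of clamped shifts, so the adjoint falls out of the shift op).
.ag_inplane_smooth <- function(node, sigma) {
  if (sigma <= 0) return(node)
  m <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-m:m)^2) / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:2) {
    shifts <- lapply(-m:m, function(j) {
      off <- integer(3)
      off[axis] <- j
      ag_shift(node, off)
    })
    node <- ag_wsum(shifts, k)
  }
  node
}

.mind_patch_half <- function(cfg) {
  ph <- (cfg@patchSize - 1L) %/% 2L
  if (cfg@mode2d) c(ph, ph, 0L) else c(ph, ph, ph)
}

.mind_epsilon <- function(cfg, data) {
  if (cfg@epsilon > 0) return(cfg@epsilon)
  rng <- diff(range(data))
  max(cfg@epsilonScale * rng^2, .Machine$double.xmin)
}

#' MINDDescriptor: dense per-voxel descriptor responses
#'
#' @slot values 4D array `(nx, ny, nz, |R|)`; per voxel, one response in
#'   `(0, 1]` per search-region offset, with the per-voxel maximum
#'   normalized to 1.
#' @slot offsets integer matrix of the search-region offsets (rows),
#'   aligned with the 4th dimension of `values`.
#' @slot config the generating [MindConfig-class].
#' @exportClass MINDDescriptor
setClass("MINDDescriptor",
  representation(values = "array", offsets = "matrix", config = "MindConfig"))

setValidity("MINDDescriptor", function(object) {
  msg <- character()
  v <- object@values
  if (length(dim(v)) != 4L)
    msg <- c(msg, "values must be a 4D array")
  if (any(v <= 0) || any(v > 1 + 1e-12))
    msg <- c(msg, "responses must lie in (0, 1]")
  if (dim(v)[4] != nrow(object@offsets))
    msg <- c(msg, "4th dimension must match the number of offsets")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MINDDescriptor", function(object) {
  d <- dim(object@values)
  cat(sprintf("MINDDescriptor: %d x %d x %d voxels, %d offsets (%s)\n",
              d[1], d[2], d[3], d[4],
              if (object@config@mode2d) "in-plane" else "3D"))
})

#' Per-voxel patch distance
#'
#' Reference (per-voxel) evaluation of the patch dissimilarity
#' `D(I, x, r)`: the summed squared difference between the patch at `x`
#' and the patch at `x + r`, with clamped reads at the grid boundary.
#' The dense descriptor evaluates the same quantity vectorized; this
#' scalar form is the readable definition (and the one used to
#' cross-check the dense path).
#'
#' @param v a [Volume-class].
#' @param x integer(3) voxel index, 0-based.
#' @param r integer(3) offset.
#' @param cfg a [MindConfig-class].
#' @return Non-negative scalar.
#' @export
mindPatchDistance <- function(v, x, r, cfg = mindConfig()) {
  stopifnot(is(v, "Volume"))
  img <- v@data
  if (cfg@smoothSigma > 0)
    img <- .gauss_smooth3(img, c(cfg@smoothSigma, cfg@smoothSigma, 0))
  d <- dim(img)
  half <- .mind_patch_half(cfg)
  cl <- function(p) pmin(pmax(p, c(0, 0, 0)), d - 1)
  acc <- 0
  for (px in -half[1]:half[1])
    for (py in -half[2]:half[2])
      for (pz in -half[3]:half[3]) {
        p <- cl(x + c(px, py, pz))
        q <- cl(p + r)
        acc <- acc + (img[p[1] + 1, p[2] + 1, p[3] + 1] -
                        img[q[1] + 1, q[2] + 1, q[3] + 1])^2
      }
  acc
}

#' Per-voxel variance estimate
#'
#' Mean of [mindPatchDistance()] over the variance-neighborhood offsets,
#' floored at the (automatic or configured) epsilon; strictly positive.
#'
#' @inheritParams mindPatchDistance
#' @return Positive scalar.
#' @export
mindVarianceEstimate <- function(v, x, cfg = mindConfig()) {
  stopifnot(is(v, "Volume"))
  img <- v@data
  if (cfg@smoothSigma > 0)
    img <- .gauss_smooth3(img, c(cfg@smoothSigma, cfg@smoothSigma, 0))
  eps <- .mind_epsilon(cfg, img)
  ds <- apply(cfg@varNeighborhood, 1, function(n)
    mindPatchDistance(v, x, n, cfg))
  max(mean(ds), eps)
}

# Tape-level descriptor: returns a 4D node (nx, ny, nz, |R|).
ag_mind <- function(Inode, cfg) {
  Inode <- .ag_inplane_smooth(Inode, cfg@smoothSigma)
  search <- cfg@searchRegion
  varn <- cfg@varNeighborhood
  half <- .mind_patch_half(cfg)
  eps <- .mind_epsilon(cfg, Inode$value)
  keyf <- function(m) apply(m, 1, paste, collapse = ",")
  allof <- unique(rbind(search, varn))
  Dmap <- vector("list", nrow(allof))
  names(Dmap) <- keyf(allof)
  for (i in seq_len(nrow(allof))) {
    d <- ag_sub(Inode, ag_shift(Inode, allof[i, ]))
    Dmap[[i]] <- ag_boxsum(ag_mul(d, d), half)
  }
  vkeys <- keyf(varn)
  V <- ag_clampmin(ag_smul(ag_addn(Dmap[vkeys]), 1 / length(vkeys)), eps)
  skeys <- keyf(search)
  Ms <- lapply(skeys, function(k) ag_exp(ag_smul(ag_div(Dmap[[k]], V), -1)))
  ag_norm_max_last(ag_stack4(Ms))
}

#' Compute the dense MIND descriptor of a volume
#'
#' @param v a [Volume-class], at least as large as the search-region
#'   footprint.
#' @param cfg a [MindConfig-class] (default [mindConfig()]).
#' @return A [MINDDescriptor-class].
#' @export
mindDescriptor <- function(v, cfg = mindConfig()) {
  stopifnot(is(v, "Volume"), is(cfg, "MindConfig"))
  vals <- ag_value(ag_mind(ag_const(v@data), cfg))
  new("MINDDescriptor", values = vals, offsets = cfg@searchRegion,
      config = cfg)
}

# Tape-level content loss of a (possibly differentiable) volume node
# against a fixed descriptor array.
ag_content_loss <- function(bnode, fixed_desc, cfg) {
  ag_meanabs(ag_mind(bnode, cfg), ag_const(fixed_desc))
}

#' MIND content loss between two volumes
#'
#' Mean absolute difference between the dense MIND descriptors of two
#' volumes on the same grid: the structural (modality-independent)
#' dissimilarity driving registration. Symmetric in its arguments and
#' zero for identical volumes.
#'
#' @param a,b [Volume-class] objects on the same grid.
#' @param cfg a [MindConfig-class].
#' @return A non-negative scalar.
#' @export
contentLoss <- function(a, b, cfg = mindConfig()) {
  stopifnot(is(a, "Volume"), is(b, "Volume"))
  if (!identical(dim(a@data), dim(b@data)))
    stop("contentLoss: volumes must have identical grid dimensions")
  da <- ag_value(ag_mind(ag_const(a@data), cfg))
  db <- ag_value(ag_mind(ag_const(b@data), cfg))
  mean(abs(da - db))
}
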