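# Shared fixtures and independent oracles, all built in code.

# A smooth bandlimited test volume (sum of low-frequency sinusoids).
smooth_volume <- function(d = c(16, 16, 8), spacing = c(1, 1, 1)) {
  u <- (seq_len(d[1]) - 1) / d[1]
  v <- (seq_len(d[2]) - 1) / d[2]
  w <- (seq_len(d[3]) - 1) / d[3]
  U <- array(rep(u, times = d[2] * d[3]), d)
  V <- array(rep(rep(v, each = d[1]), times = d[3]), d)
  W <- array(rep(w, each = d[1] * d[2]), d)
  Volume(sin(2 * pi * U) + 0.5 * cos(2 * pi * V) + 0.3 * sin(2 * pi * W),
         spacing = spacing)
}

# Independent brute-force MIND oracle: per-voxel loops, clamped reads
# (patch position clamped first, then the offset read clamped again).
brute_mind_at <- function(img, x, cfg) {
  d <- dim(img)
  half <- if (cfg@mode2d) c((cfg@patchSize - 1) / 2, (cfg@patchSize - 1) / 2, 0)
          else rep((cfg@patchSize - 1) / 2, 3)
  cl <- function(p) pmin(pmax(p, c(0, 0, 0)), d - 1)
  Dfun <- function(r) {
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
  eps <- if (cfg@epsilon > 0) cfg@epsilon else
    max(cfg@epsilonScale * diff(range(img))^2, .Machine$double.xmin)
  V <- max(mean(apply(cfg@varNeighborhood, 1, Dfun)), eps)
  M <- apply(cfg@searchRegion, 1, function(r) exp(-Dfun(r) / V))
  M / max(M)
}

# Integer-offset clamped shift of an array (index-shift oracle).
shift_array <- function(a, off) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax)
    pmin(pmax(seq_len(d[ax]) + off[ax], 1L), d[ax]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Constant-translation deformation field.
translation_field <- function(d, t, spacing = c(1, 1, 1)) {
  u <- array(0, c(d, 3))
  for (c in 1:3) u[, , , c] <- t[c]
  DeformationField(u, spacing = spacing)
}

# A cube mask fixture.
cube_mask <- function(d, lo, hi, label = 1L, spacing = c(1, 1, 1)) {
  a <- array(0L, d)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- label
  ROIMask(a, spacing = spacing)
}

# Small network configuration used across tests.
test_net_config <- function(inSize = c(16, 16, 8), base = 4L, nres = 1L,
                            nscales = 2L, ...) {
  networkConfig(inSize = inSize, baseChannels = base, nResBlocks = nres,
                nScales = nscales, ...)
}
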