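# Synthetic multimodal phantom generator: a shared pelvic-like anatomy
# (smooth background gradient, bladder-like ellipsoid, rectum-like
# tube, bright bone shells), a smooth fold-free random deformation
# between the pair, two intensity renderings that are non-monotone
# across tissue classes (so raw-intensity metrics fail while structure
# matches), per-modality noise, organ masks and bone landmarks.

.phantom_label_names <- c("1" = "bladder", "2" = "rectum")

# Separable Gaussian smoothing with replicate padding, per axis sigma
# in voxels (0 disables an axis).
.gauss_smooth3 <- function(arr, sigma) {
  for (a in 1:3) {
    s <- sigma[a]
    if (s <= 0) next
    m <- max(1L, ceiling(3 * s))
    k <- exp(-((-m:m)^2) / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim(arr))
    for (j in -m:m) {
      off <- integer(3)
      off[a] <- j
      acc <- acc + k[j + m + 1] * cpp_shift3d(arr, off)
    }
    arr <- acc
  }
  arr
}

# Smooth random displacement field with max in-plane magnitude equal to
# amplitude (voxels); the through-plane component is scaled by the
# spacing ratio so displacements are comparable in mm.
.random_smooth_field <- function(size, spacing, amplitude, smoothness) {
  if (amplitude == 0) return(array(0, c(size, 3L)))
  sig <- c(smoothness, smoothness, smoothness * spacing[1] / spacing[3])
  # smooth on a padded grid, then crop: keeps the field stationary
  # (replicate-padded smoothing would concentrate energy at the edges)
  m <- pmax(1L, ceiling(3 * sig))
  psize <- size + 2L * m
  crop <- function(a) a[m[1] + seq_len(size[1]), m[2] + seq_len(size[2]),
                        m[3] + seq_len(size[3]), drop = FALSE]
  comp <- lapply(1:3, function(c)
    crop(.gauss_smooth3(array(rnorm(prod(psize)), psize), sig)))
  mag <- sqrt(comp[[1]]^2 + comp[[2]]^2)
  s_inplane <- amplitude / max(mag)
  zmax <- max(abs(comp[[3]]))
  s_z <- if (zmax > 0) amplitude * spacing[1] / spacing[3] / zmax else 0
  array(c(comp[[1]] * s_inplane, comp[[2]] * s_inplane,
          comp[[3]] * s_z), c(size, 3L))
}

# Numerical inverse displacement: find gi with g(x + gi(x)) = -gi(x),
# by fixed-point iteration (converges for smooth sub-voxel-gradient
# fields).
.invert_field <- function(g, iters = 20L) {
  d <- dim(g)[1:3]
  base <- cbind(
    rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
    rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  gi <- matrix(0, nrow(base), 3)
  gcomp <- lapply(1:3, function(c) array(g[, , , c], d))
  for (it in seq_len(iters)) {
    coords <- base + gi
    for (c in 1:3)
      gi[, c] <- -cpp_sample_trilinear(gcomp[[c]], coords)
  }
  array(gi, c(d, 3L))
}

.phantom_geometry <- function(size) {
  nx <- size[1]; ny <- size[2]; nz <- size[3]
  u <- (seq_len(nx) - 1) / max(1, nx - 1)
  v <- (seq_len(ny) - 1) / max(1, ny - 1)
  w <- (seq_len(nz) - 1) / max(1, nz - 1)
  U <- array(rep(u, times = ny * nz), size)
  V <- array(rep(rep(v, each = nx), times = nz), size)
  W <- array(rep(w, each = nx * ny), size)
  list(U = U, V = V, W = W)
}

# Tissue class array: 0 background, 1 bladder, 2 rectum, 3 bone.
.phantom_classes <- function(size, nOrgans) {
  geo <- .phantom_geometry(size)
  cls <- array(0L, size)
  ell <- ((geo$U - 0.45) / 0.28)^2 + ((geo$V - 0.55) / 0.22)^2 +
    ((geo$W - 0.5) / 0.38)^2
  cls[ell <= 1] <- 1L
  if (nOrgans >= 2L) {
    tube <- ((geo$U - 0.72) / 0.1)^2 + ((geo$V - 0.28) / 0.1)^2
    cls[tube <= 1 & cls == 0L] <- 2L
  }
  centers <- rbind(c(0.15, 0.15, 0.30), c(0.85, 0.20, 0.65),
                   c(0.18, 0.85, 0.60), c(0.82, 0.82, 0.35))
  for (i in seq_len(nrow(centers))) {
    sph <- ((geo$U - centers[i, 1]) / 0.07)^2 +
      ((geo$V - centers[i, 2]) / 0.07)^2 +
      ((geo$W - centers[i, 3]) / 0.22)^2
    cls[sph <= 1 & cls == 0L] <- 3L
  }
  list(cls = cls, geo = geo, boneCenters = centers)
}

# Modality renderings: piecewise class intensities on a smooth shared
# background (ramp + soft-tissue-like texture). The geometry and the
# texture (hence the neighborhood structure) are identical between the
# modalities; the intensity mapping is non-monotone across classes —
# class ranks are permuted and the background ramp and texture are
# reversed in sign (an affine remap of modality A's background:
# invisible to MIND, hostile to intensity correlation).
.render_modality <- function(cls, geo, tex, which) {
  if (which == "A") {
    base <- 0.15 + 0.25 * geo$U + 0.1 * tex
    classInt <- c(0.45, 0.6, 1.0)  # bladder, rectum, bone
  } else {
    base <- 0.72 - 0.08 * geo$U - 0.05 * tex
    classInt <- c(0.95, 0.1, 0.5)
  }
  out <- base
  for (l in 1:3) out[cls == l] <- classInt[l]
  out
}

# Smooth zero-mean unit-sd texture shared by both modalities; real
# soft tissue is textured, and without texture the background offers a
# structure descriptor nothing to register (flat-region displacement is
# unobservable).
.phantom_texture <- function(size) {
  t <- .gauss_smooth3(array(rnorm(prod(size)), size), c(2.5, 2.5, 0.8))
  (t - mean(t)) / sd(t)
}

#' Generate one synthetic multimodal phantom case
#'
#' Builds a shared anatomy, draws a smooth random ground-truth
#' deformation (scaled so the mapping is fold-free), renders the two
#' modalities — the second from the anatomy warped by the numerical
#' inverse of the ground-truth field, so that warping volume B by
#' `gtField` brings it into alignment with volume A — adds independent
#' Gaussian noise per modality, and normalizes both volumes to
#' `[-1, 1]`. Deterministic given the config seed.
#'
#' @param cfg a [PhantomConfig-class].
#' @return A [PhantomCase-class].
#' @export
generatePhantomCase <- function(cfg = PhantomConfig()) {
  stopifnot(is(cfg, "PhantomConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  size <- cfg@size
  sp <- cfg@spacing
  g <- .random_smooth_field(size, sp, cfg@amplitude, cfg@smoothness)
  gt <- DeformationField(g, spacing = sp)
  if (cfg@amplitude > 0 && jacobianFoldingFraction(gt) > 0)
    stop("generated deformation folds; use a smaller amplitude or ",
         "larger smoothness")
  anat <- .phantom_classes(size, cfg@nOrgans)
  tex <- .phantom_texture(size)
  rendA <- .render_modality(anat$cls, anat$geo, tex, "A")
  # B anatomy: warp classes (nearest), the coordinate ramps and the
  # texture (trilinear) by the inverse field, then render.
  if (cfg@amplitude > 0) {
    gi <- .invert_field(g)
    clsB_d <- cpp_warp_fw(array(as.double(anat$cls), size), gi, TRUE)
    clsB <- array(as.integer(round(clsB_d)), size)
    geoB <- list(U = cpp_warp_fw(anat$geo$U, gi, FALSE),
                 V = cpp_warp_fw(anat$geo$V, gi, FALSE),
                 W = cpp_warp_fw(anat$geo$W, gi, FALSE))
    texB <- cpp_warp_fw(tex, gi, FALSE)
  } else {
    clsB <- anat$cls
    geoB <- anat$geo
    texB <- tex
  }
  rendB <- .render_modality(clsB, geoB, texB, "B")
  volA <- Volume(rendA + array(rnorm(prod(size), sd = cfg@noiseSd), size),
                 spacing = sp, modality = "SYNTH_A")
  volB <- Volume(rendB + array(rnorm(prod(size), sd = cfg@noiseSd), size),
                 spacing = sp, modality = "SYNTH_B")
  volA <- normalizeIntensity(volA)
  volB <- normalizeIntensity(volB)
  maskA <- ROIMask(array(ifelse(anat$cls %in% 1:2, anat$cls, 0L), size),
                   labelNames = .phantom_label_names, spacing = sp)
  maskB <- ROIMask(array(ifelse(clsB %in% 1:2, clsB, 0L), size),
                   labelNames = .phantom_label_names, spacing = sp)
  ptsA_vox <- sweep(anat$boneCenters, 2, size - 1, `*`)
  dispA <- sampleField(gt, ptsA_vox)
  ptsA_mm <- sweep(ptsA_vox, 2, sp, `*`)
  ptsB_mm <- sweep(ptsA_vox + dispA, 2, sp, `*`)
  labels <- paste0("bone", seq_len(nrow(ptsA_mm)))
  new("PhantomCase", volA = volA, volB = volB, maskA = maskA,
      maskB = maskB, gtField = gt,
      landmarksA = LandmarkSet(ptsA_mm, labels),
      landmarksB = LandmarkSet(ptsB_mm, labels), config = cfg)
}

.case_id <- function(i) sprintf("case_%03d", i)

#' Generate a phantom suite on disk
#'
#' Writes `nTrain + nTest` cases with seeds `baseSeed + i` in the
#' standard layout (`case_XXX/{a,b,mask_a,mask_b,gt_field}.nii.gz`,
#' landmark CSVs, manifest JSON recording the train/test split).
#'
#' @param outDir output directory; must be empty or absent unless
#'   `overwrite`.
#' @param nTrain,nTest non-negative case counts.
#' @param baseSeed integer; case i uses seed `baseSeed + i - 1`.
#' @param cfg template [PhantomConfig-class] (its seed is ignored).
#' @param overwrite allow writing into a non-empty directory.
#' @return Invisibly, the manifest as a list.
#' @export
generatePhantomSuite <- function(outDir, nTrain = 8L, nTest = 2L,
                                 baseSeed = 1L, cfg = PhantomConfig(),
                                 overwrite = FALSE) {
  stopifnot(nTrain >= 0L, nTest >= 0L)
  if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE): ", outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  n <- nTrain + nTest
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    ccfg <- cfg
    ccfg@seed <- as.integer(baseSeed + i - 1L)
    case <- generatePhantomCase(ccfg)
    id <- .case_id(i)
    cdir <- file.path(outDir, id)
    dir.create(cdir, showWarnings = FALSE)
    saveVolume(case@volA, file.path(cdir, "a.nii.gz"))
    saveVolume(case@volB, file.path(cdir, "b.nii.gz"))
    .write_nifti_array(case@maskA@labels, cfg@spacing, c(0, 0, 0),
                       file.path(cdir, "mask_a.nii.gz"))
    .write_nifti_array(case@maskB@labels, cfg@spacing, c(0, 0, 0),
                       file.path(cdir, "mask_b.nii.gz"))
    saveDeformationField(case@gtField, file.path(cdir, "gt_field.nii.gz"))
    writeLandmarks(case@landmarksA, file.path(cdir, "landmarks_a.csv"))
    writeLandmarks(case@landmarksB, file.path(cdir, "landmarks_b.csv"))
    cases[[i]] <- list(id = id, seed = ccfg@seed,
                       split = if (i <= nTrain) "train" else "test")
  }
  manifest <- list(
    n_train = nTrain, n_test = nTest, base_seed = baseSeed,
    size = cfg@size, spacing = cfg@spacing, amplitude = cfg@amplitude,
    smoothness = cfg@smoothness, noise_sd = cfg@noiseSd,
    label_names = as.list(.phantom_label_names),
    field_direction = paste(
      "gt_field is defined on the A grid and warps B into alignment",
      "with A: out(x) = B(x + f(x))"),
    cases = cases)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load one phantom case from a suite directory
#'
#' @param caseDir a `case_XXX` directory written by
#'   [generatePhantomSuite()].
#' @return A list with `a`, `b` (Volumes), `maskA`, `maskB`,
#'   `gtField`, `landmarksA`, `landmarksB`.
#' @export
loadPhantomCase <- function(caseDir) {
  rd <- function(f) file.path(caseDir, f)
  a <- loadVolume(rd("a.nii.gz"), modality = "SYNTH_A")
  b <- loadVolume(rd("b.nii.gz"), modality = "SYNTH_B")
  mk <- function(f) {
    raw <- .read_nifti_array(rd(f))
    ROIMask(array(as.integer(round(raw$data)), dim(raw$data)),
            labelNames = .phantom_label_names, spacing = raw$spacing)
  }
  list(a = a, b = b, maskA = mk("mask_a.nii.gz"),
       maskB = mk("mask_b.nii.gz"),
       gtField = loadDeformationField(rd("gt_field.nii.gz")),
       landmarksA = readLandmarks(rd("landmarks_a.csv")),
       landmarksB = readLandmarks(rd("landmarks_b.csv")))
}

#' Load a phantom suite written by [generatePhantomSuite()]
#'
#' @param dir suite directory containing `manifest.json`.
#' @return A list with `manifest`, `train` and `test` case lists (each
#'   case as in [loadPhantomCase()]).
#' @export
loadPhantomSuite <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("manifest not found: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  load_split <- function(split) {
    ids <- vapply(manifest$cases,
                  function(cs) if (cs$split == split) cs$id else NA_character_,
                  "")
    lapply(ids[!is.na(ids)], function(id) loadPhantomCase(file.path(dir, id)))
  }
  list(manifest = manifest, train = load_split("train"),
       test = load_split("test"))
}
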