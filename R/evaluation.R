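# Registration quality metrics: Dice overlap, symmetric average surface
# distance (mm), landmark target registration error (mm), and the
# per-case evaluation report.

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` for the voxel sets carrying `label` in the
#' two masks. Defined as 1 when both sets are empty (reported via a
#' message).
#'
#' @param a,b [ROIMask-class] objects on matching grids.
#' @param label integer label to compare.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(a, b, label = 1L) {
  stopifnot(is(a, "ROIMask"), is(b, "ROIMask"))
  if (!identical(dim(a@labels), dim(b@labels)))
    stop("dice: mask grids differ")
  av <- a@labels == label
  bv <- b@labels == label
  na <- sum(av)
  nb <- sum(bv)
  if (na + nb == 0L) {
    message("dice: both masks empty for label ", label, "; returning 1")
    return(1)
  }
  2 * sum(av & bv) / (na + nb)
}

# Surface voxels of a binary array: labeled voxels with at least one
# face-adjacent background neighbour; the outside of the grid counts as
# background, so labeled voxels on the grid edge are surface.
.surface_voxels <- function(bin) {
  d <- dim(bin)
  interior_nb <- array(TRUE, d)
  shift_and <- function(acc, axis, dir) {
    nb <- array(FALSE, d)  # FALSE = background beyond the edge
    if (d[axis] >= 2) {
      idx_to <- lapply(d, seq_len)
      idx_from <- idx_to
      if (dir > 0) {
        idx_to[[axis]] <- 1:(d[axis] - 1)
        idx_from[[axis]] <- 2:d[axis]
      } else {
        idx_to[[axis]] <- 2:d[axis]
        idx_from[[axis]] <- 1:(d[axis] - 1)
      }
      nb[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
        bin[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    }
    acc & nb
  }
  for (axis in 1:3) for (dir in c(1, -1))
    interior_nb <- shift_and(interior_nb, axis, dir)
  bin & !interior_nb
}

#' Symmetric average surface distance in mm
#'
#' The surface of a label is its voxels with a face-adjacent background
#' neighbour. For each surface voxel the nearest distance (in mm, using
#' the voxel spacing) to the other surface is found; the two directed
#' means are averaged. Two routes are available: exact pairwise search
#' and a Euclidean distance-transform fast path; they agree to within
#' numerical round-off.
#'
#' @param a,b [ROIMask-class] objects on matching grids and spacing.
#' @param label integer label to compare; must be non-empty on both
#'   sides.
#' @param method `"auto"` (distance transform for large surfaces),
#'   `"exact"` or `"edt"`.
#' @return Non-negative distance in mm.
#' @export
averageSurfaceDistance <- function(a, b, label = 1L,
                                   method = c("auto", "exact", "edt")) {
  stopifnot(is(a, "ROIMask"), is(b, "ROIMask"))
  method <- match.arg(method)
  if (!identical(dim(a@labels), dim(b@labels)))
    stop("averageSurfaceDistance: mask grids differ")
  if (max(abs(a@spacing - b@spacing)) > 1e-9)
    stop("averageSurfaceDistance: mask spacings differ")
  av <- a@labels == label
  bv <- b@labels == label
  if (!any(av)) stop("label ", label, " empty in the first mask")
  if (!any(bv)) stop("label ", label, " empty in the second mask")
  sa <- .surface_voxels(av)
  sb <- .surface_voxels(bv)
  ca <- which(sa, arr.ind = TRUE) - 1  # 0-based voxel coordinates
  cb <- which(sb, arr.ind = TRUE) - 1
  if (method == "auto")
    method <- if (nrow(ca) * nrow(cb) > 4e6) "edt" else "exact"
  if (method == "exact") {
    dab <- cpp_min_dists(ca, cb, a@spacing)
    dba <- cpp_min_dists(cb, ca, a@spacing)
  } else {
    eb <- cpp_edt_sq(as.vector(sb), dim(sb), a@spacing)
    ea <- cpp_edt_sq(as.vector(sa), dim(sa), a@spacing)
    dab <- sqrt(eb[sa])
    dba <- sqrt(ea[sb])
  }
  (mean(dab) + mean(dba)) / 2
}

#' Target registration error of paired landmarks
#'
#' The deformation follows the resampling convention (it maps fixed-grid
#' positions into moving space), so each fixed-space landmark is mapped
#' through the transform `x + f(x)` (displacement interpolated
#' trilinearly at the point, converted to mm) and compared with its
#' moving-space counterpart.
#'
#' @param fixedPts,movingPts paired [LandmarkSet-class] objects (equal
#'   length, matching labels), physical mm.
#' @param f a [DeformationField-class] whose grid covers all fixed
#'   points.
#' @param origin physical origin of the field grid in mm.
#' @return A list with `perPoint` (named mm distances) and `mean`.
#' @export
targetRegistrationError <- function(fixedPts, movingPts, f,
                                    origin = c(0, 0, 0)) {
  stopifnot(is(fixedPts, "LandmarkSet"), is(movingPts, "LandmarkSet"),
            is(f, "DeformationField"))
  if (nrow(fixedPts@points) != nrow(movingPts@points) ||
      !identical(fixedPts@labels, movingPts@labels))
    stop("landmark sets must be paired (equal length, matching labels)")
  sp <- f@spacing
  d <- dim(f@displacements)[1:3]
  vox <- sweep(sweep(fixedPts@points, 2, origin), 2, sp, `/`)
  tol <- 1e-6
  out_of_grid <- vox < -tol | sweep(vox, 2, d - 1) > tol
  if (any(out_of_grid)) {
    bad <- which(apply(out_of_grid, 1, any))
    stop("landmark(s) outside the field extent: ",
         paste(fixedPts@labels[bad], collapse = ", "))
  }
  disp <- sampleField(f, vox)
  mapped <- fixedPts@points + sweep(disp, 2, sp, `*`)
  per <- sqrt(rowSums((mapped - movingPts@points)^2))
  names(per) <- fixedPts@labels
  list(perPoint = per, mean = mean(per))
}

#' Write / read landmarks as CSV
#'
#' Columns: `label,x_mm,y_mm,z_mm`.
#'
#' @param ls a [LandmarkSet-class].
#' @param path CSV file path.
#' @return `readLandmarks` returns a [LandmarkSet-class].
#' @export
writeLandmarks <- function(ls, path) {
  stopifnot(is(ls, "LandmarkSet"))
  df <- data.frame(label = ls@labels, x_mm = ls@points[, 1],
                   y_mm = ls@points[, 2], z_mm = ls@points[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  df <- read.csv(path)
  m <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  dimnames(m) <- NULL
  LandmarkSet(m, df$label)
}

#' Evaluate registration quality on one case
#'
#' Predicts the field registering the moving (B) volume onto the fixed
#' (A) volume — or uses a supplied field — then warps the moving-side
#' masks into fixed space with nearest-neighbour interpolation and
#' reports pre- and post-registration Dice and average surface distance
#' per label, landmark TRE, and the folding fraction of the field.
#'
#' @param case a [PhantomCase-class], or a list with components `a`,
#'   `b` (Volumes) and optionally `maskA`, `maskB`, `landmarksA`,
#'   `landmarksB`; at least one of masks or landmarks is required.
#' @param state a [TrainState-class]; its B-to-A network provides the
#'   field. Ignored when `field` is given.
#' @param field optional [DeformationField-class] to evaluate in place
#'   of a prediction (e.g. a ground-truth field).
#' @param origin physical origin of the grid in mm (for landmarks).
#' @return A list: `rois` data.frame (label, name, voxels, dice_pre,
#'   dice_post, asd_pre, asd_post), `tre_pre_mm`, `tre_post_mm`,
#'   `folding_fraction`.
#' @export
evaluateCase <- function(case, state = NULL, field = NULL,
                         origin = c(0, 0, 0)) {
  if (is(case, "PhantomCase"))
    case <- list(a = case@volA, b = case@volB, maskA = case@maskA,
                 maskB = case@maskB, landmarksA = case@landmarksA,
                 landmarksB = case@landmarksB)
  has_masks <- !is.null(case$maskA) && !is.null(case$maskB)
  has_lms <- !is.null(case$landmarksA) && !is.null(case$landmarksB)
  if (!has_masks && !has_lms)
    stop("evaluateCase: need ROI masks and/or landmarks")
  if (is.null(field)) {
    stopifnot(is(state, "TrainState"))
    field <- predictField(state@netBA, case$b, case$a)
  }
  rois <- NULL
  if (has_masks) {
    warpedB <- warpVolume(case$maskB, field)
    labs <- sort(unique(as.vector(case$maskA@labels)))
    labs <- labs[labs != 0L]
    rois <- do.call(rbind, lapply(labs, function(l) {
      nm <- case$maskA@labelNames[as.character(l)]
      data.frame(
        label = l,
        name = if (is.na(nm)) paste0("label", l) else unname(nm),
        voxels = sum(case$maskA@labels == l),
        dice_pre = dice(case$maskA, case$maskB, l),
        dice_post = dice(case$maskA, warpedB, l),
        asd_pre = averageSurfaceDistance(case$maskA, case$maskB, l),
        asd_post = averageSurfaceDistance(case$maskA, warpedB, l))
    }))
  }
  tre_pre <- tre_post <- NA_real_
  if (has_lms) {
    zf <- zeroField(dim(field)[1:3], voxelSpacing(field))
    tre_pre <- targetRegistrationError(case$landmarksA, case$landmarksB,
                                       zf, origin)$mean
    tre_post <- targetRegistrationError(case$landmarksA, case$landmarksB,
                                        field, origin)$mean
  }
  list(rois = rois, tre_pre_mm = tre_pre, tre_post_mm = tre_post,
       folding_fraction = jacobianFoldingFraction(field))
}

#' Aggregate per-case evaluation reports
#'
#' @param reports list of [evaluateCase()] results.
#' @return A list with `perLabel` (mean and SD of Dice/ASD pre and post
#'   across cases, per label name) and `summary` (TRE and folding,
#'   mean and SD).
#' @export
aggregateReports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  rois <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]$rois
    if (is.null(r)) return(NULL)
    r$case <- i
    r
  }))
  perLabel <- NULL
  if (!is.null(rois)) {
    perLabel <- do.call(rbind, lapply(split(rois, rois$name), function(g) {
      data.frame(
        name = g$name[1],
        dice_pre_mean = mean(g$dice_pre), dice_pre_sd = sd(g$dice_pre),
        dice_post_mean = mean(g$dice_post), dice_post_sd = sd(g$dice_post),
        asd_pre_mean = mean(g$asd_pre), asd_pre_sd = sd(g$asd_pre),
        asd_post_mean = mean(g$asd_post), asd_post_sd = sd(g$asd_post))
    }))
    rownames(perLabel) <- NULL
  }
  g <- function(f) vapply(reports, function(r) r[[f]], 0)
  summary <- data.frame(
    tre_pre_mean = mean(g("tre_pre_mm")), tre_pre_sd = sd(g("tre_pre_mm")),
    tre_post_mean = mean(g("tre_post_mm")),
    tre_post_sd = sd(g("tre_post_mm")),
    folding_mean = mean(g("folding_fraction")),
    folding_sd = sd(g("folding_fraction")))
  list(perLabel = perLabel, summary = summary, perCase = rois)
}
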