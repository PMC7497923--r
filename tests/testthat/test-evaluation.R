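test_that("Dice matches voxel-count oracles and is symmetric", {
  d <- c(8, 8, 8)
  a <- cube_mask(d, c(3, 3, 3), c(4, 4, 4))  # 2x2x2 cube, 8 voxels
  expect_equal(dice(a, a), 1)
  b <- cube_mask(d, c(6, 6, 6), c(7, 7, 7))
  expect_equal(dice(a, b), 0)
  # same cube shifted by one voxel along x: 4 voxels overlap
  c2 <- cube_mask(d, c(4, 3, 3), c(5, 4, 4))
  expect_equal(dice(a, c2), 2 * 4 / (8 + 8))
  expect_equal(dice(c2, a), dice(a, c2))
  expect_message(
    expect_equal(dice(cube_mask(d, c(1, 1, 1), c(1, 1, 1), label = 2L),
                      cube_mask(d, c(2, 2, 2), c(2, 2, 2), label = 3L),
                      label = 9L), 1),
    "both masks empty")
  expect_error(dice(a, cube_mask(c(6, 6, 6), c(1, 1, 1), c(2, 2, 2))),
               "grids differ")
  # joint voxel permutation leaves Dice unchanged
  set.seed(41)
  p1 <- sample(d[1])
  expect_equal(dice(ROIMask(maskLabels(a)[p1, , ]),
                    ROIMask(maskLabels(c2)[p1, , ])), dice(a, c2))
})

test_that("average surface distance scales with spacing and is symmetric", {
  d <- c(9, 5, 5)
  one <- function(x, sp) cube_mask(d, c(x, 3, 3), c(x, 3, 3), spacing = sp)
  expect_equal(averageSurfaceDistance(one(2, c(1, 1, 1)), one(2, c(1, 1, 1))),
               0)
  # two single-voxel masks 3 voxels apart along x
  expect_equal(averageSurfaceDistance(one(2, c(1, 1, 1)), one(5, c(1, 1, 1))),
               3)
  expect_equal(averageSurfaceDistance(one(2, c(5, 1, 1)), one(5, c(5, 1, 1))),
               15)
  a <- cube_mask(d, c(2, 2, 2), c(4, 4, 4))
  b <- cube_mask(d, c(5, 2, 2), c(7, 4, 4))
  expect_equal(averageSurfaceDistance(a, b), averageSurfaceDistance(b, a))
  expect_error(averageSurfaceDistance(a, cube_mask(d, c(1, 1, 1), c(1, 1, 1),
                                                   label = 2L)), "empty")
})

test_that("exact and distance-transform ASD routes agree to round-off", {
  set.seed(43)
  d <- c(14, 12, 6)
  for (rep in 1:3) {
    blob <- function() {
      ctr <- c(sample(4:10, 1), sample(4:8, 1), sample(2:4, 1))
      rad <- runif(1, 1.5, 3.5)
      idx <- which(array(TRUE, d), arr.ind = TRUE)
      m <- array(0L, d)
      keep <- sqrt(colSums((t(idx) - ctr)^2)) <= rad
      m[idx[keep, , drop = FALSE]] <- 1L
      ROIMask(m, spacing = c(1, 1.5, 5))
    }
    a <- blob(); b <- blob()
    if (!any(maskLabels(a) == 1L) || !any(maskLabels(b) == 1L)) next
    expect_equal(averageSurfaceDistance(a, b, method = "exact"),
                 averageSurfaceDistance(a, b, method = "edt"),
                 tolerance = 1e-9)
  }
})

test_that("TRE follows the Pythagorean oracle and cancels a closing field", {
  d <- c(12, 12, 6)
  sp <- c(1, 1, 5)
  pts <- rbind(c(3, 4, 10), c(8, 8, 20))
  lmA <- LandmarkSet(pts, c("p1", "p2"))
  zf <- zeroField(d, sp)
  expect_equal(targetRegistrationError(lmA, lmA, zf)$mean, 0)
  lmB <- LandmarkSet(sweep(pts, 2, c(3, 4, 0), `+`), c("p1", "p2"))
  r0 <- targetRegistrationError(lmA, lmB, zf)
  expect_equal(unname(r0$perPoint), c(5, 5))
  # a uniform field translating by exactly (3, 4, 0) mm = (3, 4, 0) vox here
  closing <- translation_field(d, c(3, 4, 0), spacing = sp)
  expect_lt(targetRegistrationError(lmA, lmB, closing)$mean, 1e-6)
  out <- LandmarkSet(rbind(c(100, 0, 0)), "far")
  expect_error(targetRegistrationError(out, out, zf), "outside")
  expect_error(targetRegistrationError(lmA, LandmarkSet(pts, c("x", "y")), zf),
               "paired")
})

test_that("case evaluation is consistent with direct warping and aggregates cleanly", {
  case <- generatePhantomCase(PhantomConfig(seed = 2))
  cfg <- networkConfig(inSize = c(32, 32, 8), baseChannels = 4L,
                       nResBlocks = 1L, nScales = 3L)
  st0 <- trainRegistration(list(case), cfg, epochs = 0L, seed = 1L)
  r0 <- evaluateCase(case, st0)  # zero field: post == pre exactly
  expect_equal(r0$rois$dice_post, r0$rois$dice_pre)
  expect_equal(r0$rois$asd_post, r0$rois$asd_pre)
  expect_equal(r0$tre_post_mm, r0$tre_pre_mm)
  expect_equal(r0$folding_fraction, 0)
  # ground-truth field in place of a prediction vs direct mask warping
  rg <- evaluateCase(case, field = case@gtField)
  direct <- warpVolume(case@maskB, case@gtField)
  for (l in 1:2) {
    expect_lt(abs(rg$rois$dice_post[rg$rois$label == l] -
                    dice(case@maskA, direct, l)), 0.02)
  }
  expect_lt(rg$tre_post_mm, rg$tre_pre_mm)
  # aggregate of three identical reports equals the single report
  agg <- aggregateReports(list(rg, rg, rg))
  expect_equal(agg$perLabel$dice_post_mean,
               rg$rois$dice_post[order(rg$rois$name)])
  expect_equal(agg$perLabel$dice_post_sd, c(0, 0))
  expect_equal(agg$summary$tre_post_mean, rg$tre_post_mm)
  expect_error(evaluateCase(list(a = case@volA, b = case@volB), st0),
               "masks and/or landmarks")
})
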