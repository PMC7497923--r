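spike_volume <- function() {
  # 1D-like spike embedded in 3D: [0,0,0,10,0,0,0] along x
  a <- array(0, c(7, 5, 3))
  a[4, 3, 2] <- 10
  Volume(a)
}

test_that("patch distance matches hand-enumerated values", {
  cfg3 <- mindConfig(patchSize = 3)
  const <- Volume(array(4.2, c(6, 6, 3)))
  expect_equal(mindPatchDistance(const, c(3, 3, 1), c(2, 1, 0), cfg3), 0)
  set.seed(2)
  rnd <- Volume(array(rnorm(6 * 6 * 3), c(6, 6, 3)))
  expect_equal(mindPatchDistance(rnd, c(2, 3, 1), c(0, 0, 0), cfg3), 0)
  # spike, 3x1x1-style patch read along x only: a 3x3 in-plane patch at
  # the spike voxel vs its x+1 neighbour mismatches at two positions
  sp <- spike_volume()
  x <- c(3, 2, 1)  # 0-based spike voxel
  got <- mindPatchDistance(sp, x, c(1, 0, 0), cfg3)
  expect_equal(got, 200)  # two mismatched entries of 10^2 each
  # symmetry D(x, r) = D(x + r, -r) away from boundary effects
  expect_equal(mindPatchDistance(rnd, c(2, 2, 1), c(1, 1, 0), cfg3),
               mindPatchDistance(rnd, c(3, 3, 1), c(-1, -1, 0), cfg3))
})

test_that("variance estimate is a floored neighborhood mean of distances", {
  cfg3 <- mindConfig(patchSize = 3)
  const <- Volume(array(1, c(6, 6, 3)))
  eps <- CycleMIND:::.mind_epsilon(cfg3, volData(const))
  expect_equal(mindVarianceEstimate(const, c(3, 3, 1), cfg3), eps)
  sp <- spike_volume()
  x <- c(3, 2, 1)
  ds <- apply(cfg3@varNeighborhood, 1, function(n)
    mindPatchDistance(sp, x, n, cfg3))
  expect_equal(mindVarianceEstimate(sp, x, cfg3), mean(ds))
  expect_gt(mindVarianceEstimate(sp, x, cfg3), 0)
})

test_that("dense descriptor equals the per-voxel brute-force oracle", {
  set.seed(42)
  img <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  cfg <- mindConfig()
  vals <- CycleMIND:::ag_value(
    CycleMIND:::ag_mind(CycleMIND:::ag_const(img), cfg))
  for (x in list(c(0, 0, 0), c(3, 4, 2), c(7, 7, 3), c(1, 6, 0))) {
    expect_lt(max(abs(vals[x[1] + 1, x[2] + 1, x[3] + 1, ] -
                        brute_mind_at(img, x, cfg))), 1e-6)
  }
})

test_that("descriptor responses live in (0, 1] with per-voxel max 1", {
  set.seed(3)
  v <- Volume(array(rnorm(10 * 10 * 4), c(10, 10, 4)))
  desc <- mindDescriptor(v)
  vals <- desc@values
  expect_true(all(vals > 0 & vals <= 1))
  mx <- apply(vals, 1:3, max)
  expect_equal(as.vector(mx), rep(1, length(mx)))
  # constant image: all responses exactly 1 everywhere
  cd <- mindDescriptor(Volume(array(2, c(8, 8, 3))))
  expect_true(all(cd@values == 1))
})

test_that("content loss identities hold", {
  set.seed(8)
  v <- Volume(array(rnorm(9 * 9 * 4), c(9, 9, 4)))
  expect_equal(contentLoss(v, v), 0)
  # two constants of different values: both all-1 descriptors
  expect_equal(contentLoss(Volume(array(0, c(8, 8, 3))),
                           Volume(array(5, c(8, 8, 3)))), 0)
  w <- Volume(array(rnorm(9 * 9 * 4), c(9, 9, 4)))
  expect_equal(contentLoss(v, w), contentLoss(w, v))
  expect_error(contentLoss(v, Volume(array(0, c(8, 8, 4)))), "dimensions")
  # spike vs its global negation, against the brute-force oracle
  sp <- spike_volume()
  neg <- Volume(-volData(sp))
  cfg <- mindConfig()
  d <- dim(volData(sp))
  acc <- 0
  for (i in 0:(d[1] - 1)) for (j in 0:(d[2] - 1)) for (k in 0:(d[3] - 1))
    acc <- acc + sum(abs(brute_mind_at(volData(sp), c(i, j, k), cfg) -
                           brute_mind_at(volData(neg), c(i, j, k), cfg)))
  expected <- acc / (prod(d) * nrow(cfg@searchRegion))
  expect_equal(contentLoss(sp, neg, cfg), expected, tolerance = 1e-10)
})

test_that("structure dominates intensity: monotone remaps cost far less than misalignment", {
  case <- generatePhantomCase(PhantomConfig(seed = 3, amplitude = 0))
  I <- volData(case@volA)
  shifted <- Volume(shift_array(I, c(2, 0, 0)))
  base <- contentLoss(case@volA, shifted)
  # affine maps are exactly invisible; mild smooth nonlinearities cost
  # an order of magnitude less than a 2-voxel misalignment
  expect_equal(contentLoss(case@volA, Volume(0.4 * I - 0.2)), 0)
  for (f in list(function(x) x + 0.2 * x^3,
                 function(x) x + 0.05 * sin(pi * x))) {
    expect_lte(contentLoss(case@volA, Volume(f(I))), 0.1 * base)
  }
})

test_that("content loss decreases monotonically as a translation closes", {
  case <- generatePhantomCase(PhantomConfig(seed = 2, amplitude = 0))
  I <- volData(case@volA)
  losses <- vapply(c(3, 2, 1, 0), function(t)
    contentLoss(case@volA, Volume(shift_array(I, c(t, 0, 0)))), 0)
  expect_true(all(diff(losses) < 0))
  expect_equal(losses[4], 0)
})

test_that("3D descriptor mode uses cubic geometry", {
  cfg <- mindConfig(patchSize = 3, regionSize = 3, mode2d = FALSE)
  expect_equal(nrow(cfg@searchRegion), 26)
  expect_equal(nrow(cfg@varNeighborhood), 6)
  set.seed(12)
  img <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  vals <- CycleMIND:::ag_value(
    CycleMIND:::ag_mind(CycleMIND:::ag_const(img), cfg))
  x <- c(3, 2, 3)
  expect_lt(max(abs(vals[x[1] + 1, x[2] + 1, x[3] + 1, ] -
                      brute_mind_at(img, x, cfg))), 1e-6)
})
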