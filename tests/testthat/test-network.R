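test_that("network building is seed-deterministic and zero-initialized at the head", {
  cfg <- test_net_config()
  n1 <- buildNetwork(cfg, 7L)
  n2 <- buildNetwork(cfg, 7L)
  expect_identical(netParams(n1), netParams(n2))
  n3 <- buildNetwork(cfg, 8L)
  expect_false(identical(netParams(n1), netParams(n3)))
  set.seed(71)
  mv <- Volume(array(tanh(rnorm(16 * 16 * 8)), c(16, 16, 8)))
  fx <- Volume(array(tanh(rnorm(16 * 16 * 8)), c(16, 16, 8)))
  fld <- predictField(n1, mv, fx)
  expect_true(all(displacements(fld) == 0))
  expect_identical(volData(warpVolume(mv, fld)), volData(mv))
})

test_that("parameter count matches the closed-form architecture count", {
  cfg <- test_net_config(inSize = c(16, 16, 4), base = 4L, nres = 2L,
                         nscales = 2L)
  net <- buildNetwork(cfg, 1L)
  conv <- function(cin, cout, k = 27) k * cin * cout + cout
  expected <- conv(2, 4) + conv(4, 8) +              # down
    2 * (conv(8, 8) + conv(8, 8)) +                  # residual blocks
    conv(8, 4) + conv(4, 4) +                        # up
    conv(4, 3, k = 1)                                # head
  expect_equal(networkParameterCount(net), expected)
})

test_that("field prediction respects the shape contract and input roles", {
  cfg <- test_net_config(finalZeroInit = FALSE)
  net <- buildNetwork(cfg, 5L)
  set.seed(55)
  mv <- Volume(array(tanh(rnorm(16 * 16 * 8)), c(16, 16, 8)))
  fx <- smooth_volume(c(16, 16, 8))
  fld <- predictField(net, mv, fx)
  expect_equal(dim(displacements(fld)), c(16L, 16L, 8L, 3L))
  expect_true(all(is.finite(displacements(fld))))
  expect_true(all(abs(displacements(fld)) <= cfg@maxDisplacement))
  # swapping (moving, fixed) changes the prediction: no hidden symmetry
  swapped <- predictField(net, fx, mv)
  expect_gt(max(abs(displacements(fld) - displacements(swapped))), 1e-6)
  expect_error(predictField(net, smooth_volume(c(8, 8, 8)), fx),
               "does not match")
})

test_that("the FCN is shift-covariant at multiples of its total stride", {
  # without global normalization layers the network commutes exactly
  # with in-plane shifts by 2^nScales voxels, away from the boundary
  cfg <- networkConfig(inSize = c(64, 64, 4), baseChannels = 4L,
                       nResBlocks = 1L, nScales = 2L,
                       finalZeroInit = FALSE, norm = "none")
  net <- buildNetwork(cfg, 9L)
  set.seed(91)
  base_m <- array(tanh(rnorm(64 * 64 * 4)), c(64, 64, 4))
  base_f <- array(tanh(rnorm(64 * 64 * 4)), c(64, 64, 4))
  s <- 4L  # 2^nScales
  out0 <- displacements(predictField(net, Volume(base_m), Volume(base_f)))
  outs <- displacements(predictField(net,
    Volume(shift_array(base_m, c(s, 0, 0))),
    Volume(shift_array(base_f, c(s, 0, 0)))))
  # interior comparison, discarding a margin wider than the receptive halo
  m <- 21:(64 - 20 - s)
  expect_lt(max(abs(outs[m, , , ] - out0[m + s, , , ])), 1e-8)
})

test_that("configuration invariants are enforced", {
  expect_error(networkConfig(inSize = c(30, 32, 8)), "divisible")
  expect_error(networkConfig(inSize = c(32, 32, 8), nResBlocks = 0L), ">= 1")
  cfg <- test_net_config()
  net <- buildNetwork(cfg, 2L)
  p <- tempfile(fileext = ".rds")
  saveNetworkCheckpoint(net, p)
  net2 <- loadNetworkCheckpoint(p)
  expect_identical(netParams(net2), netParams(net))
  expect_error(loadNetworkCheckpoint(tempfile()), "not found")
})
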