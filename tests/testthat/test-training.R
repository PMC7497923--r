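# Small shared setup: a normalized smooth pair at the test input size.
train_pair <- function(d = c(16, 16, 8)) {
  a <- normalizeIntensity(smooth_volume(d), 0, 1)
  set.seed(17)
  bdat <- volData(a) * 0.8 + 0.1 * array(rnorm(prod(d)), d)
  b <- normalizeIntensity(Volume(bdat), 0, 1)
  list(a = a, b = b)
}

zero_state <- function(cfg) {
  trainRegistration(list(train_pair(cfg@inSize)), cfg, epochs = 0L,
                    seed = 1L)
}

test_that("cycle loss vanishes for identity networks and cancelling translations", {
  cfg <- test_net_config()
  p <- train_pair()
  idA <- buildNetwork(cfg, 1L)
  idB <- buildNetwork(cfg, 2L)
  expect_equal(cycleLoss(p$a, p$b, idA, idB), 0)
  # +t then -t stubs: reconstruction error within interpolation error
  fwd <- constantFieldNetwork(cfg, c(1.3, 0, 0))
  bwd <- constantFieldNetwork(cfg, c(-1.3, 0, 0))
  # two trilinear resamplings of a bandlimited volume: error is bounded
  # by twice the curvature-interpolation bound, ~2 * |f''|_max / 8
  expect_lt(cycleLoss(p$a, p$b, fwd, bwd), 0.05)
})

test_that("cycle loss of a doubled translation on a ramp matches the shift oracle", {
  cfg <- test_net_config()
  d <- cfg@inSize
  t <- 1
  ramp <- Volume(array(rep(seq(0, 1, length.out = d[1]),
                           times = d[2] * d[3]), d))
  net <- constantFieldNetwork(cfg, c(t, 0, 0))
  # both passes translate by +t: recon(x) = ramp(clamp(x + 2t))
  idx <- seq_len(d[1]) - 1
  slope <- 1 / (d[1] - 1)
  expected_prof <- pmin(idx + 2 * t, d[1] - 1) * slope
  expected <- mean(abs(expected_prof - idx * slope))
  got <- cycleLoss(ramp, ramp, net, net)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("total loss obeys its identities and matches composed term oracles", {
  cfg <- test_net_config()
  p <- train_pair()
  st0 <- zero_state(cfg)
  same <- totalLoss(p$a, p$a, st0)
  expect_equal(same$total, 0)
  expect_true(all(same$terms == 0))
  # zero weights annihilate everything
  wz <- LossWeights(0, 0, 0)
  expect_equal(totalLoss(p$a, p$b, st0, weights = wz)$total, 0)
  # constant-field stubs: compose the six term oracles by hand
  tAB <- c(0.7, -0.4, 0)
  tBA <- c(-0.5, 0.8, 0)
  stub <- new("TrainState",
              netAB = constantFieldNetwork(cfg, tAB),
              netBA = constantFieldNetwork(cfg, tBA),
              optState = list(), epoch = 0L, lossHistory = data.frame())
  w <- LossWeights(5, 1, 1)
  mind <- mindConfig()
  got <- totalLoss(p$a, p$b, stub, weights = w, mindCfg = mind,
                   regType = "magnitude")
  d <- cfg@inSize
  oracle_dir <- function(mov, fix, tf, tb) {
    f1 <- translation_field(d, tf)
    warped <- warpVolume(mov, f1)
    cont <- contentLoss(warped, fix, mind)
    reg <- regularizationLoss(f1)
    recon <- warpVolume(warped, translation_field(d, tb))
    cyc <- mean(abs(volData(recon) - volData(mov)))
    c(cont, reg, cyc)
  }
  o1 <- oracle_dir(p$b, p$a, tBA, tAB)  # B toward A, back via netAB
  o2 <- oracle_dir(p$a, p$b, tAB, tBA)
  expect_equal(unname(got$terms), c(o1, o2), tolerance = 1e-6)
  expected_total <- sum(c(o1, o2) * c(5, 1, 1, 5, 1, 1))
  expect_equal(got$total, expected_total, tolerance = 1e-6)
  # weight-zero ablation: with lambda_cyc = 0 the total reduces exactly
  wnc <- LossWeights(5, 1, 0)
  gnc <- totalLoss(p$a, p$b, stub, weights = wnc, mindCfg = mind,
                    regType = "magnitude")
  expect_equal(gnc$total, sum(c(o1[1:2], o2[1:2]) * c(5, 1, 5, 1)),
               tolerance = 1e-6)
})

test_that("training is seed-deterministic and 0 epochs is a no-op", {
  cfg <- test_net_config()
  p <- train_pair()
  st0 <- trainRegistration(list(p), cfg, epochs = 0L, seed = 3L)
  expect_identical(netParams(st0@netAB), netParams(buildNetwork(cfg, 3L)))
  expect_identical(netParams(st0@netBA), netParams(buildNetwork(cfg, 4L)))
  expect_equal(st0@epoch, 0L)
  expect_equal(nrow(st0@lossHistory), 0L)
  s1 <- trainRegistration(list(p), cfg, epochs = 3L, lr = 1e-3, seed = 5L)
  s2 <- trainRegistration(list(p), cfg, epochs = 3L, lr = 1e-3, seed = 5L)
  expect_identical(s1@lossHistory, s2@lossHistory)
  expect_identical(netParams(s1@netAB), netParams(s2@netAB))
})

test_that("short training on one deformed pair reduces the loss and stays finite", {
  case <- generatePhantomCase(PhantomConfig(size = c(16, 16, 8),
                                            amplitude = 2, smoothness = 5,
                                            seed = 23))
  cfg <- test_net_config()
  st <- trainRegistration(list(case), cfg, weights = LossWeights(5, 1, 1),
                          epochs = 40L, lr = 1e-3, seed = 2L)
  h <- st@lossHistory
  expect_true(all(is.finite(as.matrix(h[, -(1:2)]))))
  expect_true(all(as.matrix(h[, CycleMIND:::.term_names]) >= 0))
  first <- h$total[1]
  last <- mean(h$total[(nrow(h) - 4):nrow(h)])
  expect_lt(last, first)
  # frozen smoke threshold from the recorded reference run
  expect_lt(last / first, 0.98)
})
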