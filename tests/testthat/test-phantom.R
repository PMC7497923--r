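test_that("phantom generation is bit-deterministic in its seed", {
  c1 <- generatePhantomCase(PhantomConfig(seed = 6))
  c2 <- generatePhantomCase(PhantomConfig(seed = 6))
  expect_identical(volData(c1@volA), volData(c2@volA))
  expect_identical(volData(c1@volB), volData(c2@volB))
  expect_identical(displacements(c1@gtField), displacements(c2@gtField))
  expect_identical(landmarkPoints(c1@landmarksB), landmarkPoints(c2@landmarksB))
  c3 <- generatePhantomCase(PhantomConfig(seed = 7))
  expect_false(identical(volData(c1@volA), volData(c3@volA)))
})

test_that("zero amplitude yields an identical, perfectly overlapping pair", {
  c0 <- generatePhantomCase(PhantomConfig(seed = 4, amplitude = 0))
  expect_true(all(displacements(c0@gtField) == 0))
  expect_equal(dice(c0@maskA, c0@maskB, 1), 1)
  expect_equal(dice(c0@maskA, c0@maskB, 2), 1)
  expect_identical(maskLabels(c0@maskA), maskLabels(c0@maskB))
})

test_that("default phantoms sit in the calibrated difficulty band and never fold", {
  for (s in 1:3) {
    case <- generatePhantomCase(PhantomConfig(seed = s))
    expect_equal(jacobianFoldingFraction(case@gtField), 0)
    for (l in 1:2) {
      d <- dice(case@maskA, case@maskB, l)
      expect_gte(d, 0.5)
      expect_lte(d, 0.95)
    }
    expect_true(all(abs(volData(case@volA)) <= 1))
    expect_true(all(abs(volData(case@volB)) <= 1))
  }
})

test_that("ground-truth field brings the moving side back into alignment", {
  for (s in 1:2) {
    case <- generatePhantomCase(PhantomConfig(seed = s))
    back <- warpVolume(case@maskB, case@gtField)
    for (l in 1:2) expect_gte(dice(case@maskA, back, l), 0.95)
    # landmarks: B points are A points displaced by the sampled field
    tre <- targetRegistrationError(case@landmarksA, case@landmarksB,
                                   case@gtField)
    expect_lt(tre$mean, 1e-9)
  }
})

test_that("the modality challenge defeats intensity but not structure", {
  c0 <- generatePhantomCase(PhantomConfig(seed = 3, amplitude = 0))
  r <- cor(as.vector(volData(c0@volA)), as.vector(volData(c0@volB)))
  expect_lt(abs(r), 0.5)
  cl_ab <- contentLoss(c0@volA, c0@volB)
  # comparator: a fresh acquisition of the same anatomy. Both sides of
  # the cross-modal pair carry independent noise (difference-noise SD
  # sqrt(2) x the rendering noise after normalization, ~0.05), so the
  # added noise here is matched to that level.
  set.seed(99)
  noisy <- Volume(volData(c0@volA) +
                    array(rnorm(prod(dim(c0@volA)), sd = 0.05),
                          dim(c0@volA)))
  expect_lte(cl_ab, 2 * contentLoss(c0@volA, noisy))
})

test_that("suites round-trip through disk with an exact manifest", {
  dir0 <- file.path(tempdir(), "suite0")
  unlink(dir0, recursive = TRUE)
  m0 <- generatePhantomSuite(dir0, nTrain = 0L, nTest = 0L, baseSeed = 1L)
  expect_equal(length(m0$cases), 0L)
  expect_equal(list.files(dir0), "manifest.json")
  dir1 <- file.path(tempdir(), "suite1")
  unlink(dir1, recursive = TRUE)
  cfg <- PhantomConfig(size = c(16, 16, 8))
  m1 <- generatePhantomSuite(dir1, nTrain = 3L, nTest = 1L, baseSeed = 5L,
                             cfg = cfg)
  expect_equal(length(list.dirs(dir1, recursive = FALSE)), 4L)
  expect_equal(vapply(m1$cases, `[[`, 0L, "seed"), 5:8)
  expect_error(generatePhantomSuite(dir1, 1L, 0L, 1L, cfg), "not empty")
  suite <- loadPhantomSuite(dir1)
  expect_equal(length(suite$train), 3L)
  expect_equal(length(suite$test), 1L)
  # files round-trip exactly against the in-memory generator
  ref <- generatePhantomCase({cc <- cfg; cc@seed <- 5L; cc})
  expect_identical(volData(suite$train[[1]]$a), volData(ref@volA))
  expect_identical(maskLabels(suite$train[[1]]$maskB), maskLabels(ref@maskB))
  expect_identical(displacements(suite$train[[1]]$gtField),
                   displacements(ref@gtField))
  expect_equal(landmarkPoints(suite$train[[1]]$landmarksB),
               landmarkPoints(ref@landmarksB))
  # a second run with the same base seed reproduces identical content
  dir2 <- file.path(tempdir(), "suite2")
  unlink(dir2, recursive = TRUE)
  generatePhantomSuite(dir2, nTrain = 3L, nTest = 1L, baseSeed = 5L,
                       cfg = cfg)
  s2 <- loadPhantomSuite(dir2)
  expect_identical(volData(s2$test[[1]]$b), volData(suite$test[[1]]$b))
  unlink(c(dir0, dir1, dir2), recursive = TRUE)
})

test_that("excessive amplitude is rejected with actionable advice", {
  expect_error(generatePhantomCase(PhantomConfig(seed = 1, amplitude = 12,
                                                 smoothness = 2)),
               "smaller amplitude")
})
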