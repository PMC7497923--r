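test_that("volumes round-trip bit-exactly through NIfTI and MetaImage", {
  set.seed(11)
  v <- Volume(array(rnorm(6 * 6 * 3), c(6, 6, 3)), spacing = c(1, 1, 5),
              origin = c(2, -3, 10), modality = "CT")
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    saveVolume(v, f)
    v2 <- loadVolume(f, modality = "CT")
    expect_identical(volData(v2), volData(v))
    expect_equal(voxelSpacing(v2), c(1, 1, 5))
    expect_equal(volOrigin(v2), c(2, -3, 10))
  }
  w <- Volume(array(runif(8), c(2, 2, 2)), spacing = c(2, 2, 2))
  f <- tempfile(fileext = ".nii.gz")
  saveVolume(w, f)
  expect_equal(voxelSpacing(loadVolume(f)), c(2, 2, 2))
})

test_that("a hand-written MetaImage header is parsed with its geometry", {
  # header-writing oracle: bytes laid out independently of the package
  f <- tempfile(fileext = ".mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(f))
  writeLines(c("ObjectType = Image", "NDims = 3",
               "BinaryData = True", "BinaryDataByteOrderMSB = False",
               "DimSize = 8 8 4", "ElementSpacing = 1 1 5",
               "Offset = 0 0 0", "ElementType = MET_FLOAT",
               paste("ElementDataFile =", raw_name)), f)
  vals <- seq_len(8 * 8 * 4) / 7
  con <- file(file.path(dirname(f), raw_name), "wb")
  writeBin(vals, con, size = 4L, endian = "little")
  close(con)
  v <- loadVolume(f)
  expect_equal(dim(v), c(8L, 8L, 4L))
  expect_equal(voxelSpacing(v), c(1, 1, 5))
  expect_equal(volData(v)[2, 1, 1], vals[2], tolerance = 1e-7)
})

test_that("I/O rejects NaN/Inf and unreadable inputs with clear errors", {
  bad <- Volume(array(c(NaN, rnorm(7)), c(2, 2, 2)))
  expect_error(saveVolume(bad, tempfile(fileext = ".nii.gz")), "NaN/Inf")
  expect_error(loadVolume(tempfile(fileext = ".nii.gz")), "not found")
  # NaN in a file (written by the header-writing oracle) is caught at load
  f <- tempfile(fileext = ".mha")
  con <- file(f, "wb")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 2 2 2",
               "ElementSpacing = 1 1 1", "ElementType = MET_DOUBLE",
               "ElementDataFile = LOCAL"), con)
  writeBin(c(NaN, rep(1, 7)), con, size = 8L, endian = "little")
  close(con)
  expect_error(loadVolume(f), "NaN/Inf")
  # missing spacing metadata
  f2 <- tempfile(fileext = ".mhd")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 2 2 2",
               "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"), f2)
  expect_error(loadVolume(f2), "ElementSpacing")
})

test_that("resampling is exact on fixed points and matches a ramp analytically", {
  set.seed(4)
  v <- Volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 5))
  expect_identical(volData(resampleVolume(v, c(1, 1, 5))), volData(v))
  const <- Volume(array(3.5, c(5, 6, 4)), spacing = c(2, 2, 2))
  r <- resampleVolume(const, c(1.3, 0.7, 3))
  expect_true(all(volData(r) == 3.5))
  # axis-aligned linear ramp, resampled 2x finer in x
  d <- c(8, 4, 3)
  ramp <- Volume(array(rep(0:7, times = d[2] * d[3]), d),
                 spacing = c(2, 2, 2))
  fine <- resampleVolume(ramp, c(1, 2, 2))
  expect_equal(dim(fine), c(16L, 4L, 3L))
  j <- 0:14  # inside the input extent; the last voxel extrapolates (clamp)
  expect_lt(max(abs(volData(fine)[j + 1, 1, 1] - j / 2)), 1e-6)
})

test_that("down-up resampling of a bandlimited volume is within the interpolation bound", {
  v <- smooth_volume(c(24, 24, 8), spacing = c(1, 1, 2))
  back <- resampleVolume(resampleVolume(v, c(0.5, 0.5, 1)), c(1, 1, 2))
  expect_equal(dim(back), dim(v))
  expect_lt(max(abs(volData(back) - volData(v))), 0.05)
})

test_that("crop/pad centers correctly, pads with air, and restores interiors", {
  set.seed(5)
  v <- Volume(array(rnorm(10 * 10 * 4), c(10, 10, 4)))
  expect_identical(volData(cropOrPad(v, c(10, 10, 4))), volData(v))
  # single bright voxel at 0-based (7,7,2): centroid crop must keep it
  a <- array(0, c(10, 10, 4))
  a[8, 8, 3] <- 10
  cc <- cropOrPad(Volume(a), c(4, 4, 4), "foreground_centroid")
  expect_equal(max(volData(cc)), 10)
  # padding a constant uses the air value (its own constant)
  pad <- cropOrPad(Volume(array(2.5, c(4, 4, 4))), c(6, 6, 6))
  expect_true(all(volData(pad) == 2.5))
  # crop then pad back recovers the original interior exactly
  cr <- cropOrPad(v, c(6, 6, 4))
  re <- cropOrPad(cr, c(10, 10, 4))
  expect_identical(volData(re)[3:8, 3:8, ], volData(v)[3:8, 3:8, ])
})

test_that("intensity normalization maps percentiles to [-1, 1] as an affine map", {
  v <- Volume(array(c(0, 50, 100, 50, 50, 50, 50, 50), c(8, 1, 1)))
  out <- volData(normalizeIntensity(v, 0, 1))
  expect_equal(out[1:3, 1, 1], c(-1, 0, 1))
  # values spanning [qlo, qhi] linearly span [-1, 1] linearly
  lin <- Volume(array(seq(-4, 8, length.out = 64), c(4, 4, 4)))
  nl <- volData(normalizeIntensity(lin, 0, 1))
  expect_equal(range(nl), c(-1, 1))
  expect_lt(max(abs(diff(as.vector(nl)) - diff(as.vector(nl))[1])), 1e-12)
  expect_warning(zz <- normalizeIntensity(Volume(array(7, c(3, 3, 3)))),
                 "constant")
  expect_true(all(volData(zz) == 0))
  # idempotent on its own output (min/max percentiles)
  set.seed(6)
  r <- Volume(array(rnorm(500), c(10, 10, 5)))
  n1 <- normalizeIntensity(r, 0, 1)
  n2 <- normalizeIntensity(n1, 0, 1)
  expect_lt(max(abs(volData(n2) - volData(n1))), 1e-12)
  expect_true(all(abs(volData(n1)) <= 1))
})
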