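test_that("a CT series reads back sorted by patient z regardless of file order", {
  d1 <- withr::local_tempdir()
  fx <- write_ct_fixture(d1, shuffle = FALSE)
  ct <- read_ct_series(d1)
  expect_equal(ct$slice_positions, c(0, 3, 6))
  expect_identical(dim(ct$voxels), c(3L, 8L, 8L))
  expect_equal(ct$voxels[2, , ], fx$vols[[2]] * 1.0)

  d2 <- withr::local_tempdir()
  write_ct_fixture(d2, shuffle = TRUE)
  ct2 <- read_ct_series(d2)
  expect_equal(ct2$voxels, ct$voxels)
  expect_equal(ct2$slice_positions, ct$slice_positions)
})

test_that("rescale slope and intercept are applied to stored values", {
  d <- withr::local_tempdir()
  fx <- write_ct_fixture(d, slope = 2, intercept = -1024)
  ct <- read_ct_series(d)
  expect_equal(ct$voxels[1, , ], 2 * fx$vols[[1]] - 1024)
  expect_true(ct$rescaled)
})

test_that("a directory mixing two series is rejected", {
  d <- withr::local_tempdir()
  write_ct_fixture(d, uid = "1.2.3.4.5")
  px <- matrix(1L, 8, 8)
  write_ct_slice(file.path(d, "other.dcm"), "9.8.7.6", z = 9, px)
  expect_error(read_ct_series(d), "more than one series")
})

test_that("square contours rasterize to exact voxel counts, holes included", {
  d <- withr::local_tempdir()
  write_ct_fixture(d)
  ct <- read_ct_series(d)
  # pixel centers at 0..7 mm; edges half a pixel outside a 2x2 block
  sq <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  ss <- structure(list(structures = list(
    box = list(list(xy = sq(-0.5, -0.5, 1.5, 1.5), z = 0)),
    ring = list(list(xy = sq(-0.5, -0.5, 4.5, 4.5), z = 3),
                list(xy = sq(0.5, 0.5, 2.5, 2.5), z = 3)))),
    class = "structure_set")
  m1 <- rasterize(ss, "box", ct)
  expect_identical(sum(m1$voxels), 4L)
  expect_identical(sum(m1$voxels[1, 1:2, 1:2]), 4L)
  # outer 5x5 fill minus inner 2x2 hole, via even-odd parity
  m2 <- rasterize(ss, "ring", ct)
  expect_identical(sum(m2$voxels), 25L - 4L)
  # union of a structure with itself under two names is idempotent
  ss2 <- structure(list(structures = list(a = ss$structures$box,
                                          b = ss$structures$box)),
                   class = "structure_set")
  expect_identical(rasterize(ss2, c("a", "b"), ct)$voxels, m1$voxels)
})

test_that("rasterization agrees with a brute-force point-in-polygon oracle", {
  d <- withr::local_tempdir()
  zs <- 0
  dir.create(d, showWarnings = FALSE)
  px <- matrix(0L, 20, 20)
  write_ct_slice(file.path(d, "s.dcm"), "1.1", 0, px)
  ct <- read_ct_series(d)
  set.seed(42)
  for (rep in 1:5) {
    xy <- random_polygon(sample(5:9, 1), cx = runif(1, 6, 12),
                         cy = runif(1, 6, 12), rmin = 2, rmax = 7)
    ss <- structure(list(structures = list(p = list(list(xy = xy, z = 0)))),
                    class = "structure_set")
    got <- rasterize(ss, "p", ct)$voxels[1, , ]
    want <- matrix(0L, 20, 20)
    for (r in 1:20) for (cc in 1:20)
      want[r, cc] <- as.integer(pip_naive(cc - 1, r - 1, xy))
    expect_identical(got, want)
  }
})

test_that("contours that match no slice name the offending structure", {
  d <- withr::local_tempdir()
  write_ct_fixture(d)
  ct <- read_ct_series(d)
  ss <- structure(list(structures = list(
    lung = list(list(xy = cbind(c(0, 2, 2), c(0, 0, 2)), z = 9.5)))),
    class = "structure_set")
  expect_error(rasterize(ss, "lung", ct), "lung")
})

test_that("mask boolean algebra obeys the set laws", {
  set.seed(1)
  d <- c(4, 6, 6)
  a <- array(rbinom(prod(d), 1, 0.5), d)
  b <- array(rbinom(prod(d), 1, 0.5), d)
  expect_identical(sum(boolean_combine(a, a, "difference")), 0L)
  empty <- array(0L, d)
  expect_identical(boolean_combine(a, empty, "union"), array(as.integer(a), d))
  expect_identical(boolean_combine(a, b, "union"), boolean_combine(b, a, "union"))
  expect_identical(boolean_combine(a, b, "intersection"),
                   boolean_combine(b, a, "intersection"))
  notb <- array(1L - b, d)
  expect_identical(boolean_combine(a, b, "difference"),
                   boolean_combine(a, notb, "intersection"))
  expect_error(boolean_combine(a, array(0L, c(4, 6, 5)), "union"), "differ")
  # phantom construction identity: (lung u airway) minus airway = lung mask
  ph <- generate_phantom(phantom_config(grid_shape = c(12, 24, 24)))
  expect_identical(
    boolean_combine(boolean_combine(ph$mask, ph$tube_mask, "union"),
                    ph$tube_mask, "difference"),
    ph$mask)
})

test_that("normalize_case enforces the target geometry exactly", {
  # identity: already at target with an identity window
  set.seed(2)
  v <- array(sample(0:255, 32 * 32 * 32, replace = TRUE), c(32, 32, 32))
  m <- array(rbinom(32^3, 1, 0.2), c(32, 32, 32))
  nc <- normalize_case(v, m, target = c(32, 32, 32), window = c(0, 255))
  expect_identical(nc$volume, array(as.integer(v), dim(v)))
  expect_identical(nc$mask, array(as.integer(m), dim(m)))

  # nearest-neighbour mask resize preserves a constant mask
  ones <- array(1L, c(8, 64, 64))
  nc2 <- normalize_case(array(7, c(8, 64, 64)), ones, target = c(8, 16, 16))
  expect_true(all(nc2$mask == 1L))

  # 64 slices reduce by the uniform index rule round(i * 63/31)
  v64 <- array(0, c(64, 8, 8))
  for (z in 1:64) v64[z, , ] <- z - 1
  nc3 <- normalize_case(v64, NULL, target = c(32, 8, 8), window = c(0, 255))
  want <- round((0:31) * 63 / 31)
  expect_equal(nc3$volume[, 1, 1], want)

  # short stacks are zero-padded symmetrically
  v20 <- array(100, c(20, 8, 8))
  m20 <- array(1L, c(20, 8, 8))
  nc4 <- normalize_case(v20, m20, target = c(32, 8, 8), window = c(0, 255))
  expect_identical(dim(nc4$volume), c(32L, 8L, 8L))
  expect_true(all(nc4$volume[1:6, , ] == 0))
  expect_true(all(nc4$mask[1:6, , ] == 0L))
  expect_true(all(nc4$mask[7:26, , ] == 1L))

  # an empty mask only warns
  expect_warning(
    normalize_case(array(1, c(8, 8, 8)), array(0L, c(8, 8, 8)),
                   target = c(8, 8, 8)),
    "empty")
})

test_that("PNG stacks round-trip losslessly and reject non-binary masks", {
  set.seed(3)
  vol <- array(sample(0:255, 4 * 16 * 16, replace = TRUE), c(4, 16, 16))
  msk <- array(rbinom(4 * 16 * 16, 1, 0.4), c(4, 16, 16))
  d <- withr::local_tempdir()
  write_png_stack(list(volume = vol, mask = msk, meta = list(seed = 9)), d)
  back <- read_png_stack(d)
  expect_identical(back$volume, array(as.integer(vol), dim(vol)))
  expect_identical(back$mask, array(as.integer(msk), dim(msk)))
  expect_equal(back$meta$seed, "9")
  # a mask slice containing grey value 7 is invalid
  bad <- matrix(0, 16, 16); bad[3, 3] <- 7 / 255
  png::writePNG(bad, file.path(d, "msk_001.png"))
  expect_error(read_png_stack(d), "0/255")
})
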