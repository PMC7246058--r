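test_that("2D U-Nets preserve shape, bound outputs and reproduce initializations", {
  set.seed(21)
  for (i in 1:3) {
    n_down <- sample(1:2, 1)
    size <- sample(c(16L, 32L), 1)
    ch <- sample(3:6, n_down + 1, replace = TRUE)
    spec <- unet2d_spec(input_size = c(size, size), n_down = n_down,
                        channels = ch)
    m <- build_unet2d(spec, seed = i)
    x <- array(runif(size * size * 2), c(size, size, 2, 1))
    r <- lungseg:::unet_forward(m, x)
    expect_identical(dim(r$p), dim(x))
    expect_true(all(r$p > 0 & r$p < 1))
    expect_identical(as.integer(r$bottleneck), bottleneck_shape(spec))
    m2 <- build_unet2d(spec, seed = i)
    expect_identical(m$params, m2$params)
  }
  expect_error(unet2d_spec(input_size = c(100, 100), n_down = 3,
                           channels = c(4, 8, 16, 16)), "divisible")
  expect_error(unet2d_spec(channels = c(4, 8)), "length")
  expect_error(unet2d_spec(dropout_rate = 1), "dropout")
})

test_that("3D specs validate the kernel menu, channel cap and pooling schedule", {
  expect_error(unet3d_spec(channels = c(48, 97, 193, 386, 900)), "cap")
  expect_error(unet3d_spec(kernels = rep(list(c(3, 3, 3)), 5)), "menu")
  expect_error(unet3d_spec(pooling = list(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2),
                                          c(2, 2, 2)),
                           channels = c(4, 8, 8, 8, 8)),
               "8x8x8")
  # a valid non-canonical input with its own schedule
  sp <- unet3d_spec(input_size = c(8, 16, 16),
                    pooling = list(c(1, 2, 2), c(2, 2, 2)),
                    channels = c(3, 4, 5),
                    kernels = list(c(1, 3, 3), c(2, 3, 3), c(1, 1, 1)))
  expect_identical(bottleneck_shape(sp), c(4L, 4L, 4L))
  m <- build_unet3d(sp, seed = 4)
  x <- array(runif(8 * 16 * 16), c(8, 16, 16, 1, 1))
  r <- lungseg:::unet_forward(m, x)
  expect_identical(dim(r$p), dim(x))
  expect_identical(as.integer(r$bottleneck), c(4L, 4L, 4L))
  expect_true(all(r$p > 0 & r$p < 1))
})

test_that("parameter counts match a layer-by-layer arithmetic oracle", {
  sp <- unet3d_spec(input_size = c(4, 8, 8), pooling = list(c(1, 2, 2)),
                    channels = c(4, 8),
                    kernels = list(c(1, 3, 3), c(2, 3, 3)))
  m <- build_unet3d(sp, seed = 1)
  conv3 <- function(k, ic, oc) prod(k) * ic * oc + oc  # weights + bias
  bn <- function(oc) 2 * oc
  want <- conv3(c(1, 3, 3), 1, 4) + bn(4) + conv3(c(1, 3, 3), 4, 4) + bn(4) +  # enc1
    conv3(c(2, 3, 3), 4, 8) + bn(8) + conv3(c(2, 3, 3), 8, 8) + bn(8) +        # bottleneck
    conv3(c(1, 3, 3), 12, 4) + bn(4) + conv3(c(1, 3, 3), 4, 4) + bn(4) +       # dec1
    (4 + 1)                                                                    # 1x1x1 head
  expect_identical(n_params(m), want)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(31)
  fw <- lungseg:::unet_forward
  spec <- unet2d_spec(input_size = c(8, 8), n_down = 1, channels = c(3, 4),
                      dropout_rate = 0)
  m <- build_unet2d(spec, seed = 2)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  g <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 2, 1))
  lossfn <- function(mm) {
    r <- fw(mm, x, train = TRUE)
    lungseg:::soft_loss_batch(r$p, g)$loss
  }
  r <- fw(m, x, train = TRUE)
  sl <- lungseg:::soft_loss_batch(r$p, g)
  gr <- lungseg:::unet_backward(m, r$caches, sl$dp)
  eps <- 1e-5
  for (k in sample(names(m$params), 6)) {
    i <- sample(length(m$params[[k]]), 1)
    mp <- m; mp$params[[k]][i] <- mp$params[[k]][i] + eps
    mm <- m; mm$params[[k]][i] <- mm$params[[k]][i] - eps
    num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
    expect_equal(gr[[k]][i], num, tolerance = 1e-3)
  }
})

test_that("predict_case thresholds and preserves slice order", {
  spec <- unet2d_spec(input_size = c(16, 16), n_down = 1, channels = c(3, 4))
  m <- build_unet2d(spec, seed = 5)
  vol <- array(sample(0:255, 3 * 16 * 16, replace = TRUE), c(3, 16, 16))
  expect_true(all(predict_case(m, vol, threshold = 1.01) == 0L))
  expect_true(all(predict_case(m, vol, threshold = 0) == 1L))
  # slice-by-slice application: each output slice equals a single-slice run
  full <- predict_case(m, vol)
  for (z in 1:3) {
    single <- predict_case(m, vol[z, , , drop = FALSE])
    expect_identical(full[z, , ], single[1, , ])
  }
  expect_error(predict_case(m, array(0, c(3, 8, 8))), "does not match")
})

test_that("checkpoints round-trip through save_model/load_model", {
  spec <- unet2d_spec(input_size = c(16, 16), n_down = 1, channels = c(3, 4))
  m <- build_unet2d(spec, seed = 6)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".spec.txt")))
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  vol <- array(128L, c(2, 16, 16))
  expect_identical(predict_case(m, vol), predict_case(m2, vol))
})
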