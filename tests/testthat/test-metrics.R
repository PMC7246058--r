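test_that("overlap reproduces the worked 8-voxel example and the conventions", {
  a <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  b <- array(c(1, 1, 0, 0, 1, 1, 0, 0), c(2, 2, 2))
  o <- overlap(a, b)
  expect_equal(o$size_a, 4)
  expect_equal(o$size_b, 4)
  expect_equal(o$intersection, 2)
  expect_equal(o$union, 6)
  expect_equal(o$dsc, 0.5)
  expect_equal(o$iou, 1 / 3)
  expect_equal(o$loss, 2 - 5 / 6)

  same <- overlap(a, a)
  expect_equal(c(same$dsc, same$iou, same$loss), c(1, 1, 0))
  disj <- overlap(a, array(1 - a, dim(a)))
  expect_equal(c(disj$dsc, disj$iou, disj$loss), c(0, 0, 2))
  both_empty <- overlap(array(0, c(2, 2)), array(0, c(2, 2)))
  expect_equal(c(both_empty$dsc, both_empty$iou, both_empty$loss), c(1, 1, 0))

  expect_error(overlap(a, array(0, c(2, 4))), "differ")
  expect_error(overlap(array(2, c(2, 2)), array(0, c(2, 2))), "binary")
})

test_that("overlap matches index-set counting and the Dice-Jaccard identity", {
  set.seed(11)
  for (i in 1:300) {
    d <- sample(2:16, 3, replace = TRUE)
    a <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.9)), d)
    b <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.9)), d)
    o <- overlap(a, b)
    ia <- which(a == 1); ib <- which(b == 1)
    ni <- length(intersect(ia, ib))
    nu <- length(union(ia, ib))
    expect_equal(o$intersection, ni)
    expect_equal(o$union, nu)
    if (length(ia) + length(ib) > 0) {
      expect_equal(o$dsc, 2 * ni / (length(ia) + length(ib)))
      expect_equal(o$iou, ni / nu)
    }
    expect_equal(o$dsc, 2 * o$iou / (1 + o$iou), tolerance = 1e-12)
    o2 <- overlap(b, a)
    expect_equal(c(o$dsc, o$iou, o$loss), c(o2$dsc, o2$iou, o2$loss))
  }
})

test_that("dsc and iou never decrease when the intersection grows at fixed sizes", {
  # |A| = |B| = 8 in a 4x4x4 grid; slide B over A to vary the intersection
  base <- array(0, c(4, 4, 4)); base[1:8] <- 1
  prev_dsc <- -1; prev_iou <- -1
  for (shift in 7:0) {
    b <- array(0, c(4, 4, 4)); b[(1:8) + shift] <- 1
    o <- overlap(base, b)
    expect_gte(o$dsc, prev_dsc)
    expect_gte(o$iou, prev_iou)
    prev_dsc <- o$dsc; prev_iou <- o$iou
  }
})

test_that("soft loss honours its limits and the closed-form sums", {
  g <- array(rbinom(64, 1, 0.5), c(4, 4, 4))
  expect_equal(soft_loss(g, g), 0)
  inv <- array(1 - g, dim(g))
  expect_gt(soft_loss(inv, g), 2 - 1e-4)
  # hand evaluation: p uniform 0.5, g = half of 32 voxels
  p <- array(0.5, c(4, 8)); gh <- array(rep(c(1, 0), each = 16), c(4, 8))
  eps <- 1e-6
  i <- 0.5 * 16; sp <- 16; sg <- 16; u <- sp + sg - i; s <- sp + sg
  want <- 2 - (i + eps) / (u + eps) - (2 * i + eps) / (s + eps)
  expect_equal(soft_loss(p, gh), want, tolerance = 1e-12)
  expect_error(soft_loss(array(1.2, c(2, 2)), array(0, c(2, 2))), "\\[0, 1\\]")
})

test_that("soft loss on binary maps agrees with the hard loss", {
  set.seed(12)
  for (i in 1:100) {
    d <- sample(2:10, 3, replace = TRUE)
    a <- array(rbinom(prod(d), 1, 0.5), d)
    b <- array(rbinom(prod(d), 1, 0.5), d)
    expect_equal(soft_loss(b, a), overlap(a, b)$loss, tolerance = 1e-5)
    sl <- soft_loss(b, a)
    expect_gte(sl, 0); expect_lte(sl, 2)
  }
})

test_that("cohort summaries match a direct formula evaluation", {
  expect_error(summarize_dsc(0.5), "n < 2")
  s0 <- summarize_dsc(rep(0.7, 5))
  expect_equal(s0$mean, 0.7); expect_equal(s0$sd, 0)
  expect_equal(c(s0$ci_low, s0$ci_high), c(0.7, 0.7))
  s1 <- summarize_dsc(c(0.9, 1.0))
  expect_equal(s1$mean, 0.95); expect_equal(s1$median, 0.95)

  set.seed(13)
  x <- runif(32, 0.8, 1)
  s <- summarize_dsc(x)
  m <- sum(x) / 32
  sdv <- sqrt(sum((x - m)^2) / 31)
  half <- qt(0.975, 31) * sdv / sqrt(32)
  expect_equal(s$mean, m, tolerance = 1e-12)
  expect_equal(s$sd, sdv, tolerance = 1e-12)
  expect_equal(s$ci_low, m - half, tolerance = 1e-12)
  expect_equal(s$ci_high, m + half, tolerance = 1e-12)
  expect_equal(s$max, max(x)); expect_equal(s$min, min(x))
  expect_equal(s$median, median(x))
  expect_true(s$min <= s$median && s$median <= s$max)
  expect_true(s$ci_low <= s$mean && s$mean <= s$ci_high)
})
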