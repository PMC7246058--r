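test_that("fold splits are balanced, covering, disjoint and deterministic", {
  ids <- sprintf("case_%03d", 1:200)
  sp <- make_folds(ids, k = 5, seed = 9)
  sizes <- table(sp$assignment)
  expect_identical(as.integer(sizes), rep(40L, 5))
  for (f in 1:5)
    expect_identical(sum(sp$assignment != f), 160L)
  expect_identical(make_folds(ids, k = 5, seed = 9)$assignment, sp$assignment)
  expect_false(identical(make_folds(ids, k = 5, seed = 10)$assignment,
                         sp$assignment))

  sp10 <- make_folds(letters[1:10], k = 5, seed = 1)
  expect_identical(as.integer(table(sp10$assignment)), rep(2L, 5))
  expect_error(make_folds(letters[1:4], k = 5, seed = 1), "at least")

  set.seed(77)
  for (i in 1:5) {
    n <- sample(5:60, 1)
    s <- make_folds(seq_len(n), k = 5, seed = i)
    sz <- tabulate(s$assignment, 5)
    expect_identical(sum(sz), n)
    expect_lte(max(sz) - min(sz), 1L)
  }
})

test_that("augmentation yields the four stated variants and flips are involutions", {
  cs <- tiny_cohort(1)[[1]]
  aug <- augment_case(cs$volume, cs$mask)
  expect_length(aug, 4)
  expect_identical(aug[[1]]$volume, cs$volume)
  # left-right flip applied twice restores the original
  flip2 <- augment_case(aug[[2]]$volume, aug[[2]]$mask)
  expect_identical(flip2[[2]]$volume, cs$volume)
  expect_identical(flip2[[2]]$mask, cs$mask)
  # intensity inversion touches the volume only
  expect_identical(aug[[3]]$mask, cs$mask)
  expect_identical(aug[[3]]$volume, 255L - cs$volume)
  # combined variant = flip + inversion
  expect_identical(aug[[4]]$volume, 255L - aug[[2]]$volume)
  expect_identical(aug[[4]]$mask, aug[[2]]$mask)
})

test_that("DSC is invariant under a simultaneous left-right flip", {
  cs <- tiny_cohort(2)
  a <- cs[[1]]$mask
  b <- cs[[2]]$mask
  X <- dim(a)[3]
  fa <- a[, , X:1]; fb <- b[, , X:1]
  expect_equal(overlap(a, b)$dsc, overlap(fa, fb)$dsc)
})

test_that("majority voting matches its counting oracle and the worked example", {
  # three 1-votes against two 0-votes elect 1
  one <- array(1L, c(1, 1, 1)); zero <- array(0L, c(1, 1, 1))
  expect_identical(ensemble_vote(list(one, one, one, zero, zero))[1], 1L)
  expect_identical(ensemble_vote(list(one, zero, zero, zero, one))[1], 0L)

  set.seed(14)
  for (i in 1:20) {
    masks <- lapply(1:5, function(j) array(rbinom(16, 1, 0.5), c(1, 4, 4)))
    expect_identical(ensemble_vote(masks), naive_vote(masks))
  }
  m <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
  expect_identical(ensemble_vote(rep(list(m), 5)), array(as.integer(m), dim(m)))
  masks <- lapply(1:5, function(j) array(rbinom(27, 1, 0.5), c(3, 3, 3)))
  expect_identical(ensemble_vote(masks), ensemble_vote(rev(masks)))
  # even k: ties go to background
  expect_identical(ensemble_vote(list(one, zero))[1], 0L)
  expect_error(ensemble_vote(list(one, array(0L, c(2, 1, 1)))), "differ")
})

test_that("zero-epoch training returns the untouched initialization", {
  cases <- tiny_cohort(3)
  split <- make_folds(names(cases), k = 3, seed = 1)
  spec <- unet2d_spec(input_size = c(16, 16), n_down = 1, channels = c(3, 4))
  cfg <- train_config(epochs = 0, seed = 8)
  fm <- train_fold(spec, 1L, split, cases, cfg)
  init <- build_unet2d(spec, seed = 8 + 1)
  expect_identical(fm$model$params, init$params)
  expect_identical(nrow(fm$history), 0L)
})

test_that("validation cases never enter the training portion", {
  cases <- tiny_cohort(5)
  split <- make_folds(names(cases), k = 5, seed = 2)
  spec <- unet2d_spec(input_size = c(16, 16), n_down = 1, channels = c(3, 4))
  fm <- train_fold(spec, 2L, split, cases,
                   train_config(epochs = 1, learning_rate = 0.01, seed = 1))
  expect_length(intersect(fm$train_ids, fm$val_ids), 0)
  expect_setequal(c(fm$train_ids, fm$val_ids), names(cases))
  expect_identical(sort(fm$val_ids),
                   sort(names(which(split$assignment == 2))))
})

test_that("a short run reduces the training loss for both network kinds", {
  cases <- tiny_cohort(3)
  split <- make_folds(names(cases), k = 3, seed = 1)
  spec2 <- unet2d_spec(input_size = c(16, 16), n_down = 1, channels = c(4, 8))
  fm2 <- train_fold(spec2, 3L, split, cases,
                    train_config(learning_rate = 0.01, epochs = 6,
                                 batch_size = 8, seed = 4))
  expect_lt(fm2$history$train_loss[6], fm2$history$train_loss[1])
  expect_true(all(is.finite(fm2$history$val_loss)))

  spec3 <- unet3d_spec(input_size = c(8, 16, 16),
                       pooling = list(c(1, 2, 2), c(2, 2, 2)),
                       channels = c(4, 8, 8),
                       kernels = list(c(1, 3, 3), c(2, 3, 3), c(2, 3, 3)))
  fm3 <- train_fold(spec3, 3L, split, cases,
                    train_config(learning_rate = 0.01, epochs = 5,
                                 batch_size = 2, seed = 4))
  expect_lt(fm3$history$train_loss[5], fm3$history$train_loss[1])
})

test_that("the learning-rate search returns a grid member consistent with its logs", {
  cases <- tiny_cohort(4)
  split <- make_folds(names(cases), k = 4, seed = 3)
  spec <- unet2d_spec(input_size = c(16, 16), n_down = 1, channels = c(3, 4))
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 2)
  expect_identical(as.numeric(lr_search(spec, split, cases, grid = 0.01,
                                        cfg = cfg)), 0.01)
  grid <- c(0.03, 0.001)
  best <- lr_search(spec, split, cases, grid = grid, cfg = cfg)
  expect_true(as.numeric(best) %in% grid)
  losses <- attr(best, "val_loss")
  expect_identical(as.numeric(best), grid[which.min(losses)])
})
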