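#' Random k-fold partition of case ids
#'
#' Shuffles the ids with the given seed and chunks the shuffled order into
#' `k` contiguous folds whose sizes differ by at most one (200 cases with
#' k = 5 gives five folds of 40, leaving 160 training cases per fold).
#'
#' @param case_ids character or integer vector of unique case ids.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return A `fold_split`: list with `k`, named integer `assignment`
#'   (case id -> fold), and `seed`.
#' @export
make_folds <- function(case_ids, k = 5L, seed = 1L) {
  n <- length(case_ids)
  if (anyDuplicated(case_ids)) stop0("case ids must be unique")
  if (n < k) stop0("need at least k cases for k folds")
  set.seed(seed)
  ord <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- integer(n)
  fold[ord] <- rep(seq_len(k), times = sizes)
  structure(list(k = as.integer(k),
                 assignment = stats::setNames(fold, as.character(case_ids)),
                 seed = as.integer(seed)),
            class = "fold_split")
}

#' Four-fold augmentation of one case
#'
#' Returns the original pair, the left-right flip (column-axis reversal of
#' both volume and mask), the intensity inversion `v -> 255 - v` (volume
#' only — the mask is a label image and keeps its meaning), and the
#' combination of both.
#'
#' @param volume integer array (slices, rows, cols), values in \[0, 255\].
#' @param mask binary array of the same shape.
#' @return List of 4 `list(volume, mask)` pairs.
#' @export
augment_case <- function(volume, mask) {
  X <- dim(volume)[3]
  flip <- function(a) a[, , rev(seq_len(X)), drop = FALSE]
  invert <- function(a) {
    out <- 255 - a
    storage.mode(out) <- storage.mode(a)
    out
  }
  list(list(volume = volume, mask = mask),
       list(volume = flip(volume), mask = flip(mask)),
       list(volume = invert(volume), mask = mask),
       list(volume = invert(flip(volume)), mask = flip(mask)))
}

#' Training hyperparameters
#'
#' @param learning_rate Adam step size.
#' @param lr_grid candidate learning rates for [lr_search()]; the broad
#'   default grid spans 0.3 down to 0.0001.
#' @param epochs training epochs (>= 0).
#' @param batch_size samples per optimization step (slices for 2D, volumes
#'   for 3D).
#' @param augment apply the 4-fold augmentation to training cases.
#' @param grad_clip global L2-norm bound on the gradient per step (`Inf`
#'   disables clipping). Overlap losses produce occasional large gradient
#'   spikes once predictions are nearly perfect; clipping keeps late-epoch
#'   updates from knocking a converged model off its optimum.
#' @param seed base seed; fold f trains from `seed + f`.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001,
                         lr_grid = c(0.3, 0.1, 0.03, 0.01, 0.003, 0.001,
                                     3e-04, 1e-04),
                         epochs = 20L, batch_size = 8L, augment = TRUE,
                         grad_clip = 1, seed = 1L) {
  if (learning_rate <= 0) stop0("learning_rate must be positive")
  if (epochs < 0) stop0("epochs must be >= 0")
  structure(list(learning_rate = learning_rate, lr_grid = lr_grid,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 augment = isTRUE(augment), grad_clip = as.numeric(grad_clip),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Stack cases into a network tensor (channel-last). For 2D every slice
# becomes a sample: (H, W, n_slices, 1); for 3D every case is a sample:
# (Z, Y, X, n_cases, 1).
cases_to_tensor <- function(cases, kind) {
  vols <- lapply(cases, `[[`, "volume")
  msks <- lapply(cases, `[[`, "mask")
  d <- dim(vols[[1]])
  if (kind == "unet2d") {
    S <- sum(vapply(vols, function(v) dim(v)[1], numeric(1)))
    x <- array(0, c(d[2], d[3], S, 1L))
    g <- array(0, c(d[2], d[3], S, 1L))
    s <- 0L
    for (i in seq_along(vols)) {
      Z <- dim(vols[[i]])[1]
      x[, , s + seq_len(Z), 1L] <- aperm(vols[[i]], c(2, 3, 1)) / 255
      g[, , s + seq_len(Z), 1L] <- aperm(msks[[i]], c(2, 3, 1))
      s <- s + Z
    }
  } else {
    S <- length(vols)
    x <- array(0, c(d, S, 1L))
    g <- array(0, c(d, S, 1L))
    for (i in seq_along(vols)) {
      x[, , , i, 1L] <- vols[[i]] / 255
      g[, , , i, 1L] <- msks[[i]]
    }
  }
  list(x = x, g = g)
}

take_samples <- function(tensor, idx) {
  nd <- length(dim(tensor$x))
  if (nd == 4L) list(x = tensor$x[, , idx, , drop = FALSE],
                     g = tensor$g[, , idx, , drop = FALSE])
  else list(x = tensor$x[, , , idx, , drop = FALSE],
            g = tensor$g[, , , idx, , drop = FALSE])
}

n_samples <- function(tensor) {
  d <- dim(tensor$x)
  d[length(d) - 1L]
}

# Mean per-sample loss plus the pooled (whole-tensor) soft-DSC.
eval_tensor <- function(model, tensor, batch_size = 16L) {
  n <- n_samples(tensor)
  losses <- numeric(0)
  i_tot <- 0; s_tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    b <- take_samples(tensor, idx)
    p <- unet_forward(model, b$x, train = FALSE)$p
    sl <- soft_loss_batch(p, b$g)
    losses <- c(losses, sl$per_sample)
    i_tot <- i_tot + sl$i_tot
    s_tot <- s_tot + sl$s_tot
  }
  list(loss = mean(losses), soft_dsc = (2 * i_tot + 1e-6) / (s_tot + 1e-6))
}

#' Train the model of one cross-validation fold
#'
#' Minimizes the composite soft IoU+Dice loss with Adam on all cases outside
#' `fold`, using the cases assigned to `fold` for validation. Augmentation
#' (when enabled) expands every training case into its four flip/inversion
#' variants; validation cases are never augmented and never enter a training
#' batch. Per-epoch training loss, validation loss and validation soft-DSC
#' are logged.
#'
#' @param model_spec a `unet2d_spec` or `unet3d_spec`.
#' @param fold fold index used for validation.
#' @param split a [make_folds()] result covering `cases`.
#' @param cases named list of cases (`volume`, `mask`), names = case ids.
#' @param cfg a [train_config()].
#' @return A `fold_model`: list with the trained `model`, a `history` data
#'   frame, `train_ids`, `val_ids`, and `fold`.
#' @export
train_fold <- function(model_spec, fold, split, cases, cfg = train_config()) {
  ids <- names(cases)
  if (!all(ids %in% names(split$assignment)))
    stop0("cases are not covered by the fold split")
  av <- split$assignment[ids]
  train_ids <- ids[av != fold]
  val_ids <- ids[av == fold]
  if (length(train_ids) == 0L) stop0("no training cases outside fold ", fold)

  train_cases <- cases[train_ids]
  if (cfg$augment) {
    train_cases <- unlist(lapply(train_cases, function(cs)
      augment_case(cs$volume, cs$mask)), recursive = FALSE)
  }
  kind <- if (inherits(model_spec, "unet2d_spec")) "unet2d" else "unet3d"
  tr <- cases_to_tensor(train_cases, kind)
  va <- if (length(val_ids) > 0) cases_to_tensor(cases[val_ids], kind) else NULL

  builder <- if (kind == "unet2d") build_unet2d else build_unet3d
  model <- builder(model_spec, seed = cfg$seed + fold)
  opt <- adam_init(model$params)
  n <- n_samples(tr)
  hist <- vector("list", cfg$epochs)
  if (cfg$epochs > 0) {
    set.seed(cfg$seed + 1000L * fold)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; ep_i <- 0; ep_s <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        b <- take_samples(tr, idx)
        fw <- unet_forward(model, b$x, train = TRUE)
        model <- fw$model
        sl <- soft_loss_batch(fw$p, b$g)
        if (!is.finite(sl$loss))
          stop0("training diverged (non-finite loss) at epoch ", epoch)
        grads <- unet_backward(model, fw$caches, sl$dp)
        if (is.finite(cfg$grad_clip %||% Inf))
          grads <- clip_grad_norm(grads, cfg$grad_clip)
        st <- adam_step(model$params, grads, opt, cfg$learning_rate)
        model$params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + sl$loss
        ep_i <- ep_i + sl$i_tot
        ep_s <- ep_s + sl$s_tot
        nb <- nb + 1L
      }
      va_eval <- if (!is.null(va)) eval_tensor(model, va) else
        list(loss = NA_real_, soft_dsc = NA_real_)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  train_soft_dsc = (2 * ep_i + 1e-6) / (ep_s + 1e-6),
                                  val_loss = va_eval$loss,
                                  val_soft_dsc = va_eval$soft_dsc)
    }
  }
  train_eval <- if (cfg$epochs > 0) eval_tensor(model, tr) else
    list(loss = NA_real_, soft_dsc = NA_real_)
  structure(list(model = model,
                 train_eval = train_eval,
                 history = if (cfg$epochs > 0) do.call(rbind, hist) else
                   data.frame(epoch = integer(), train_loss = numeric(),
                              train_soft_dsc = numeric(), val_loss = numeric(),
                              val_soft_dsc = numeric()),
                 train_ids = train_ids, val_ids = val_ids, fold = fold),
            class = "fold_model")
}

#' Grid search for the learning rate
#'
#' Trains one fold per grid member and returns the rate with the lowest
#' final validation loss; non-finite (diverged) runs are skipped, ties go to
#' the smaller rate.
#'
#' @param model_spec architecture spec.
#' @param split fold split; fold 1 is used for validation.
#' @param cases named case list.
#' @param grid candidate learning rates.
#' @param cfg base [train_config()] (its `learning_rate` is overridden).
#' @return Best learning rate, with the per-rate final validation losses in
#'   attribute `"val_loss"`.
#' @export
lr_search <- function(model_spec, split, cases, grid = NULL,
                      cfg = train_config()) {
  grid <- grid %||% cfg$lr_grid
  if (length(grid) == 0L) stop0("learning-rate grid is empty")
  losses <- vapply(grid, function(lr) {
    cfg$learning_rate <- lr
    fm <- tryCatch(train_fold(model_spec, 1L, split, cases, cfg),
                   error = function(e) NULL)
    if (is.null(fm) || nrow(fm$history) == 0L) return(NA_real_)
    fm$history$val_loss[nrow(fm$history)]
  }, numeric(1))
  if (all(!is.finite(losses))) stop0("all learning rates diverged")
  ok <- which(is.finite(losses))
  best <- ok[order(losses[ok], grid[ok])][1]
  structure(grid[best], val_loss = stats::setNames(losses, grid))
}

#' Per-voxel majority vote over k binary masks
#'
#' A voxel is foreground iff strictly more than half of the masks vote 1;
#' with an even number of masks a tie yields background.
#'
#' @param masks list of binary arrays of identical shape.
#' @return Binary integer array.
#' @export
ensemble_vote <- function(masks) {
  if (length(masks) == 0L) stop0("no masks to vote over")
  d <- dim(masks[[1]])
  for (m in masks) {
    if (!identical(dim(m), d)) stop0("mask shapes differ")
    if (!all(m %in% c(0, 1))) stop0("masks must be binary (0/1)")
  }
  votes <- Reduce(`+`, lapply(masks, function(m) {
    m <- as.numeric(m); dim(m) <- d; m
  }))
  out <- array(as.integer(votes > length(masks) / 2), d)
  out
}

#' Run the full k-fold cross-validation
#'
#' @inheritParams train_fold
#' @param k number of folds.
#' @param split optional pre-made split (built from `cfg$seed` otherwise).
#' @return List of `fold_model`s, one per fold.
#' @export
train_cv <- function(model_spec, cases, k = 5L, cfg = train_config(),
                     split = NULL) {
  split <- split %||% make_folds(names(cases), k = k, seed = cfg$seed)
  lapply(seq_len(split$k), function(f)
    train_fold(model_spec, f, split, cases, cfg))
}

#' Majority-vote ensemble prediction over fold models
#'
#' @param fold_models list of `fold_model`s (or bare `unet_model`s).
#' @param volume normalized case volume (slices, rows, cols).
#' @param threshold probability cut passed to [predict_case()].
#' @return Binary integer array: the per-voxel majority vote of the per-fold
#'   predictions.
#' @export
predict_ensemble <- function(fold_models, volume, threshold = 0.5) {
  masks <- lapply(fold_models, function(fm) {
    m <- if (inherits(fm, "fold_model")) fm$model else fm
    predict_case(m, volume, threshold)
  })
  ensemble_vote(masks)
}
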