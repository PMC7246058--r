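#' Declarative 2D U-Net architecture
#'
#' Encoder-decoder with `n_down` max-pooling stages, two
#' convolution+normalization+ReLU blocks per level, shape-preserving 2 x 2
#' convolutions (even kernels pad the extra zero at the high-index side),
#' dropout at the bottleneck, 2 x 2 stride-2 transposed-convolution
#' upsampling, skip concatenation per level, and a 1 x 1 sigmoid output head.
#' The canonical configuration takes 128 x 128 single-channel slices down to
#' a 16 x 16 bottleneck over three pooling stages.
#'
#' @param input_size (rows, cols) of one input slice; must be divisible by
#'   `2^n_down`.
#' @param n_down number of downsampling stages.
#' @param channels channel counts per level, encoder order, ending with the
#'   bottleneck; length `n_down + 1`.
#' @param kernel square convolution kernel extent (default 2).
#' @param dropout_rate bottleneck dropout rate in \[0, 1).
#' @param batch_norm apply batch normalization after every convolution.
#' @return A `unet2d_spec`.
#' @export
unet2d_spec <- function(input_size = c(128L, 128L), n_down = 3L,
                        channels = c(64L, 128L, 256L, 512L), kernel = 2L,
                        dropout_rate = 0.5, batch_norm = TRUE) {
  input_size <- as.integer(input_size)
  n_down <- as.integer(n_down)
  if (length(input_size) != 2L || any(input_size < 2L))
    stop0("input_size must be (rows, cols)")
  if (any(input_size %% 2L^n_down != 0L))
    stop0("input_size must be divisible by 2^n_down")
  if (length(channels) != n_down + 1L)
    stop0("channels must have length n_down + 1 (levels plus bottleneck)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop0("dropout_rate must lie in [0, 1)")
  structure(list(kind = "unet2d", input_size = input_size, n_down = n_down,
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 dropout_rate = dropout_rate, batch_norm = isTRUE(batch_norm)),
            class = c("unet2d_spec", "unet_spec"))
}

#' Declarative 3D U-Net architecture
#'
#' Volumetric encoder-decoder over (slices, rows, cols) with an anisotropic
#' per-stage pooling schedule, a menu of 1 x 3 x 3 / 2 x 3 x 3 / 1 x 1 x 1
#' convolution kernels (even z-extents pad the extra zero on the high-index
#' side), nearest-neighbour upsampling that mirrors each stage's pooling
#' factors, skip concatenation, bottleneck dropout and a sigmoid head. The
#' canonical configuration pools a 32 x 128 x 128 volume to an 8 x 8 x 8
#' bottleneck (z pooled in exactly two stages) with at most 772 channels.
#'
#' @param input_size (slices, rows, cols) of the input volume.
#' @param pooling list of per-stage pooling factors `c(z, y, x)`.
#' @param channels channel counts per level, ending with the bottleneck;
#'   length `length(pooling) + 1`; maximum capped at `max_channels`.
#' @param kernels optional list of per-level kernel extents `c(z, y, x)` from
#'   the menu; defaults to 1 x 3 x 3 for the two shallowest levels and
#'   2 x 3 x 3 below them.
#' @param dropout_rate bottleneck dropout rate in \[0, 1).
#' @param batch_norm apply batch normalization after every convolution.
#' @param max_channels channel-count cap (default 772).
#' @return A `unet3d_spec`.
#' @export
unet3d_spec <- function(input_size = c(32L, 128L, 128L),
                        pooling = list(c(1L, 2L, 2L), c(1L, 2L, 2L),
                                       c(2L, 2L, 2L), c(2L, 2L, 2L)),
                        channels = c(48L, 97L, 193L, 386L, 772L),
                        kernels = NULL,
                        dropout_rate = 0.5, batch_norm = TRUE,
                        max_channels = 772L) {
  input_size <- as.integer(input_size)
  if (length(input_size) != 3L) stop0("input_size must be (slices, rows, cols)")
  n_down <- length(pooling)
  if (length(channels) != n_down + 1L)
    stop0("channels must have length length(pooling) + 1")
  if (max(channels) > max_channels)
    stop0("channel counts exceed the cap of ", max_channels)
  kernels <- kernels %||% lapply(seq_len(n_down + 1L), function(l)
    if (l <= 2L) c(1L, 3L, 3L) else c(2L, 3L, 3L))
  menu <- list(c(1L, 3L, 3L), c(2L, 3L, 3L), c(1L, 1L, 1L))
  for (k in kernels)
    if (!any(vapply(menu, identical, logical(1), as.integer(k))))
      stop0("kernel ", paste(k, collapse = "x"),
            " is not in the menu {1x3x3, 2x3x3, 1x1x1}")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop0("dropout_rate must lie in [0, 1)")
  prods <- Reduce(`*`, lapply(pooling, as.integer))
  if (any(input_size %% prods != 0L))
    stop0("pooling schedule does not divide the input size")
  bottleneck <- input_size %/% prods
  if (identical(input_size, c(32L, 128L, 128L)) &&
      !identical(bottleneck, c(8L, 8L, 8L)))
    stop0("pooling schedule must reduce a 32x128x128 input to an 8x8x8 bottleneck")
  structure(list(kind = "unet3d", input_size = input_size,
                 n_down = n_down, pooling = lapply(pooling, as.integer),
                 channels = as.integer(channels),
                 kernels = lapply(kernels, as.integer),
                 dropout_rate = dropout_rate, batch_norm = isTRUE(batch_norm),
                 max_channels = as.integer(max_channels)),
            class = c("unet3d_spec", "unet_spec"))
}

#' Spatial size of the bottleneck feature map
#' @param spec a `unet2d_spec` or `unet3d_spec`.
#' @return Integer vector of bottleneck spatial dimensions.
#' @export
bottleneck_shape <- function(spec) {
  if (inherits(spec, "unet2d_spec"))
    as.integer(spec$input_size %/% 2L^spec$n_down)
  else as.integer(spec$input_size %/% Reduce(`*`, spec$pooling))
}

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

add_conv2 <- function(params, bn_state, prefix, kern, ic, oc, batch_norm) {
  for (j in 1:2) {
    wdims <- c(kern, kern, ic, oc)
    fan <- prod(wdims[-length(wdims)])
    params[[paste0(prefix, "_c", j, "_W")]] <- he_init(wdims, fan)
    params[[paste0(prefix, "_c", j, "_b")]] <- numeric(oc)
    if (batch_norm) {
      params[[paste0(prefix, "_bn", j, "_g")]] <- rep(1, oc)
      params[[paste0(prefix, "_bn", j, "_b")]] <- numeric(oc)
      bn_state[[paste0(prefix, "_bn", j)]] <- list(mean = numeric(oc), var = rep(1, oc))
    }
    ic <- oc
  }
  list(params = params, bn_state = bn_state)
}

#' Build a trainable 2D U-Net
#'
#' Initializes all parameters (He-normal weights, zero biases, unit
#' batch-norm scale) from the given seed; identical `(spec, seed)` pairs
#' yield bit-identical initial parameters.
#'
#' @param spec a [unet2d_spec()].
#' @param seed integer seed for weight initialization.
#' @return A `unet_model`.
#' @export
build_unet2d <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet2d_spec"))
  set.seed(seed)
  params <- list(); bn_state <- list()
  L <- spec$n_down; ch <- spec$channels; k <- spec$kernel
  ic <- 1L
  for (l in seq_len(L)) {
    r <- add_conv2(params, bn_state, paste0("enc", l), k, ic, ch[l],
                   spec$batch_norm)
    params <- r$params; bn_state <- r$bn_state
    ic <- ch[l]
  }
  r <- add_conv2(params, bn_state, "bot", k, ic, ch[L + 1], spec$batch_norm)
  params <- r$params; bn_state <- r$bn_state
  for (l in rev(seq_len(L))) {
    up_in <- if (l == L) ch[L + 1] else ch[l + 1]
    params[[paste0("dec", l, "_up_W")]] <- he_init(c(2, 2, up_in, ch[l]), up_in)
    params[[paste0("dec", l, "_up_b")]] <- numeric(ch[l])
    r <- add_conv2(params, bn_state, paste0("dec", l), k, 2L * ch[l], ch[l],
                   spec$batch_norm)
    params <- r$params; bn_state <- r$bn_state
  }
  params[["head_W"]] <- array(rnorm(ch[1], 0, sqrt(1 / ch[1])), c(1, 1, ch[1], 1))
  params[["head_b"]] <- 0
  structure(list(kind = "unet2d", spec = spec, params = params,
                 bn_state = bn_state, seed = as.integer(seed)),
            class = "unet_model")
}

#' Build a trainable 3D U-Net
#' @param spec a [unet3d_spec()].
#' @param seed integer seed for weight initialization.
#' @return A `unet_model`.
#' @export
build_unet3d <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet3d_spec"))
  set.seed(seed)
  params <- list(); bn_state <- list()
  L <- spec$n_down; ch <- spec$channels
  add3 <- function(prefix, kern, ic, oc) {
    for (j in 1:2) {
      wdims <- c(kern, ic, oc)
      params[[paste0(prefix, "_c", j, "_W")]] <<- he_init(wdims, prod(kern) * ic)
      params[[paste0(prefix, "_c", j, "_b")]] <<- numeric(oc)
      if (spec$batch_norm) {
        params[[paste0(prefix, "_bn", j, "_g")]] <<- rep(1, oc)
        params[[paste0(prefix, "_bn", j, "_b")]] <<- numeric(oc)
        bn_state[[paste0(prefix, "_bn", j)]] <<- list(mean = numeric(oc), var = rep(1, oc))
      }
      ic <- oc
    }
  }
  ic <- 1L
  for (l in seq_len(L)) {
    add3(paste0("enc", l), spec$kernels[[l]], ic, ch[l])
    ic <- ch[l]
  }
  add3("bot", spec$kernels[[L + 1]], ic, ch[L + 1])
  for (l in rev(seq_len(L))) {
    up_in <- if (l == L) ch[L + 1] else ch[l + 1]
    add3(paste0("dec", l), spec$kernels[[l]], up_in + ch[l], ch[l])
  }
  params[["head_W"]] <- array(rnorm(ch[1], 0, sqrt(1 / ch[1])), c(1, 1, 1, ch[1], 1))
  params[["head_b"]] <- 0
  structure(list(kind = "unet3d", spec = spec, params = params,
                 bn_state = bn_state, seed = as.integer(seed)),
            class = "unet_model")
}

conv_block_fw <- function(model, prefix, j, h, train, keep) {
  p <- model$params
  fw <- if (model$kind == "unet2d") conv2d_fw else conv3d_fw
  cv <- fw(h, p[[paste0(prefix, "_c", j, "_W")]],
           p[[paste0(prefix, "_c", j, "_b")]], keep)
  h <- cv$y
  bn <- NULL
  if (model$spec$batch_norm) {
    key <- paste0(prefix, "_bn", j)
    bn <- bn_fw(h, p[[paste0(key, "_g")]], p[[paste0(key, "_b")]],
                model$bn_state[[key]], train)
    model$bn_state[[key]] <- bn$state
    h <- bn$y
  }
  rl <- relu_fw(h)
  list(h = rl$y, model = model,
       cache = if (keep) list(conv = cv$cache, bn = bn$cache, relu = rl$cache) else NULL)
}

conv_block_bw <- function(model, prefix, j, cache, dh, grads) {
  dh <- relu_bw(cache$relu, dh)
  if (model$spec$batch_norm) {
    b <- bn_bw(cache$bn, dh)
    key <- paste0(prefix, "_bn", j)
    grads[[paste0(key, "_g")]] <- b$dgamma
    grads[[paste0(key, "_b")]] <- b$dbeta
    dh <- b$dx
  }
  bw <- if (model$kind == "unet2d") conv2d_bw else conv3d_bw
  cb <- bw(cache$conv, dh)
  grads[[paste0(prefix, "_c", j, "_W")]] <- cb$dW
  grads[[paste0(prefix, "_c", j, "_b")]] <- cb$db
  list(dh = cb$dx, grads = grads)
}

# Forward pass. x: (H, W, N, 1) for 2D, (Z, Y, X, N, 1) for 3D, values in
# [0, 1]. Returns probabilities the same shape as x plus caches for backward.
unet_forward <- function(model, x, train = FALSE, keep = train) {
  spec <- model$spec
  L <- spec$n_down
  is2d <- model$kind == "unet2d"
  caches <- list(enc = vector("list", L), dec = vector("list", L))
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    cc <- list()
    for (j in 1:2) {
      r <- conv_block_fw(model, paste0("enc", l), j, h, train, keep)
      h <- r$h; model <- r$model; cc[[j]] <- r$cache
    }
    skips[[l]] <- h
    d <- dim(h)
    if (is2d) {
      mp <- maxpool2d_cpp(h, c(d[1], d[2], d[3] * d[4], 1L), 2L, 2L)
      od <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
    } else {
      pl <- spec$pooling[[l]]
      mp <- maxpool3d_cpp(h, c(d[1], d[2], d[3], d[4] * d[5], 1L),
                          pl[1], pl[2], pl[3])
      od <- c(d[1] %/% pl[1], d[2] %/% pl[2], d[3] %/% pl[3], d[4], d[5])
    }
    h <- mp$y
    dim(h) <- od
    caches$enc[[l]] <- list(blocks = cc, pool_idx = mp$idx, in_dim = d)
  }
  cc <- list()
  for (j in 1:2) {
    r <- conv_block_fw(model, "bot", j, h, train, keep)
    h <- r$h; model <- r$model; cc[[j]] <- r$cache
  }
  bott <- dim(h)[seq_len(if (is2d) 2 else 3)]
  dr <- dropout_fw(h, spec$dropout_rate, train)
  h <- dr$y
  caches$bot <- list(blocks = cc, dropout = dr$cache)
  for (l in rev(seq_len(L))) {
    if (is2d) {
      W <- model$params[[paste0("dec", l, "_up_W")]]
      b <- model$params[[paste0("dec", l, "_up_b")]]
      d <- dim(h)
      up <- convtrans2d_fw_cpp(h, as.integer(d), W, as.integer(dim(W)), b)
      dim(up) <- c(d[1] * 2L, d[2] * 2L, d[3], dim(W)[4])
      upc <- if (keep) list(x = h, d = d, W = W) else NULL
    } else {
      pl <- spec$pooling[[l]]
      d <- dim(h)
      up <- upsample3d_cpp(h, c(d[1], d[2], d[3], d[4] * d[5], 1L),
                           pl[1], pl[2], pl[3])
      dim(up) <- c(d[1] * pl[1], d[2] * pl[2], d[3] * pl[3], d[4], d[5])
      upc <- if (keep) list(d = d) else NULL
    }
    skip <- skips[[l]]
    h <- concat_channels(skip, up)
    c1 <- dim(skip)[length(dim(skip))]
    cc <- list()
    for (j in 1:2) {
      r <- conv_block_fw(model, paste0("dec", l), j, h, train, keep)
      h <- r$h; model <- r$model; cc[[j]] <- r$cache
    }
    caches$dec[[l]] <- list(up = upc, c1 = c1, blocks = cc)
    skips[[l]] <- NULL
  }
  fw <- if (is2d) conv2d_fw else conv3d_fw
  hd <- fw(h, model$params[["head_W"]], model$params[["head_b"]], keep)
  p <- sigmoid_fw(hd$y)
  caches$head <- if (keep) list(conv = hd$cache, p = p) else NULL
  list(p = p, caches = if (keep) caches else NULL, model = model,
       bottleneck = bott)
}

# Backward pass from the gradient of the loss w.r.t. the probability map.
unet_backward <- function(model, caches, dp) {
  spec <- model$spec
  L <- spec$n_down
  is2d <- model$kind == "unet2d"
  grads <- list()
  p <- caches$head$p
  dz <- dp * p * (1 - p)
  bw <- if (is2d) conv2d_bw else conv3d_bw
  hb <- bw(caches$head$conv, dz)
  grads[["head_W"]] <- hb$dW
  grads[["head_b"]] <- hb$db
  dh <- hb$dx
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    dc <- caches$dec[[l]]
    for (j in 2:1) {
      r <- conv_block_bw(model, paste0("dec", l), j, dc$blocks[[j]], dh, grads)
      dh <- r$dh; grads <- r$grads
    }
    sp <- split_channels(dh, dc$c1)
    dskips[[l]] <- sp$a
    dup <- sp$b
    if (is2d) {
      u <- dc$up
      r <- convtrans2d_bw_cpp(u$x, as.integer(u$d), u$W,
                              as.integer(dim(u$W)), dup)
      grads[[paste0("dec", l, "_up_W")]] <- array(r$dw, dim(u$W))
      grads[[paste0("dec", l, "_up_b")]] <- r$db
      dh <- array(r$dx, u$d)
    } else {
      pl <- spec$pooling[[l]]
      dd <- dim(dup)
      dh <- sumpool3d_cpp(dup, c(dd[1], dd[2], dd[3], dd[4] * dd[5], 1L),
                          pl[1], pl[2], pl[3])
      dim(dh) <- dc$up$d
    }
  }
  dh <- dropout_bw(caches$bot$dropout, dh)
  for (j in 2:1) {
    r <- conv_block_bw(model, "bot", j, caches$bot$blocks[[j]], dh, grads)
    dh <- r$dh; grads <- r$grads
  }
  for (l in rev(seq_len(L))) {
    ec <- caches$enc[[l]]
    dpool <- numeric(prod(ec$in_dim))
    dpool[ec$pool_idx] <- dh
    dh <- array(dpool, ec$in_dim) + dskips[[l]]
    for (j in 2:1) {
      r <- conv_block_bw(model, paste0("enc", l), j, ec$blocks[[j]], dh, grads)
      dh <- r$dh; grads <- r$grads
    }
  }
  grads
}

#' Number of trainable parameters in a model
#' @param model a `unet_model`.
#' @return Integer count of scalar parameters.
#' @export
n_params <- function(model) sum(vapply(model$params, length, numeric(1)))

#' Predict a binary mask for one normalized case
#'
#' A 2D model is applied slice-by-slice (slices batched along the sample
#' axis, output restacked in input order); a 3D model consumes the whole
#' volume. Intensities are scaled from \[0, 255\] to \[0, 1\] on input and
#' the probability map is thresholded into a binary mask.
#'
#' @param model a `unet_model`.
#' @param volume integer/numeric array (slices, rows, cols) with values in
#'   \[0, 255\] whose in-plane (and, for 3D, slice) dimensions match the
#'   model's input size.
#' @param threshold probability cut for voxel membership (default 0.5).
#' @return Binary integer array of the same shape as `volume`.
#' @export
predict_case <- function(model, volume, threshold = 0.5) {
  d <- dim(volume)
  if (length(d) != 3L) stop0("volume must be (slices, rows, cols)")
  spec <- model$spec
  if (model$kind == "unet2d") {
    if (!identical(as.integer(d[2:3]), spec$input_size))
      stop0("in-plane size ", d[2], "x", d[3],
            " does not match the model input ",
            paste(spec$input_size, collapse = "x"))
    x <- array(aperm(volume, c(2, 3, 1)) / 255, c(d[2], d[3], d[1], 1L))
    p <- unet_forward(model, x, train = FALSE)$p
    mask <- aperm(array(p >= threshold, c(d[2], d[3], d[1])), c(3, 1, 2))
  } else {
    if (!identical(as.integer(d), spec$input_size))
      stop0("volume size does not match the model input ",
            paste(spec$input_size, collapse = "x"))
    x <- array(volume / 255, c(d, 1L, 1L))
    p <- unet_forward(model, x, train = FALSE)$p
    mask <- array(p >= threshold, d)
  }
  array(as.integer(mask), d)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is R's native serialized container; alongside it a
#' plain-text `.spec.txt` records the architecture so it can be rebuilt
#' without code changes.
#' @param model a `unet_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  spec <- model$spec
  lines <- c(paste0("kind=", spec$kind),
             paste0("input_size=", paste(spec$input_size, collapse = "x")),
             paste0("channels=", paste(spec$channels, collapse = ",")),
             paste0("dropout_rate=", spec$dropout_rate),
             paste0("batch_norm=", spec$batch_norm),
             paste0("seed=", model$seed))
  if (spec$kind == "unet3d") {
    lines <- c(lines,
               paste0("pooling=", paste(vapply(spec$pooling, paste,
                                               character(1), collapse = "x"),
                                        collapse = ";")),
               paste0("kernels=", paste(vapply(spec$kernels, paste,
                                               character(1), collapse = "x"),
                                        collapse = ";")))
  } else {
    lines <- c(lines, paste0("n_down=", spec$n_down),
               paste0("kernel=", spec$kernel))
  }
  writeLines(lines, paste0(path, ".spec.txt"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
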