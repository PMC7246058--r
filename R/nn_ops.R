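# Low-level network primitives. Feature maps are column-major R arrays with
# the sample axis before a trailing channel axis: 2D (H, W, N, C),
# 3D (Z, Y, X, N, C). This layout lets convolution matmul results, channel
# concatenation and batch-norm statistics all work without transposes.
# Convolutions are stride-1 and shape-preserving; for an even kernel extent
# the extra zero-pad goes on the high-index side (low pad = floor((k-1)/2)).

conv2d_fw <- function(x, W, b, keep = TRUE) {
  d <- dim(x); wd <- dim(W)
  cols <- im2col2d_cpp(x, as.integer(d), wd[1], wd[2],
                       (wd[1] - 1L) %/% 2L, (wd[2] - 1L) %/% 2L)
  ymat <- cols %*% matrix(W, ncol = wd[4])
  add_bias_cpp(ymat, b)
  y <- ymat
  dim(y) <- c(d[1], d[2], d[3], wd[4])
  list(y = y,
       cache = if (keep) list(cols = cols, W = W, d = d, wd = wd) else NULL)
}

conv2d_bw <- function(cache, dy) {
  d <- cache$d; wd <- cache$wd
  dym <- dy
  dim(dym) <- c(prod(d[1:3]), wd[4])
  wmat <- matrix(cache$W, ncol = wd[4])
  dW <- array(crossprod(cache$cols, dym), dim = wd)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, wmat)
  dx <- col2im2d_cpp(dcols, as.integer(d), wd[1], wd[2],
                     (wd[1] - 1L) %/% 2L, (wd[2] - 1L) %/% 2L)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

conv3d_fw <- function(x, W, b, keep = TRUE) {
  d <- dim(x); wd <- dim(W)
  cols <- im2col3d_cpp(x, as.integer(d), wd[1], wd[2], wd[3],
                       (wd[1] - 1L) %/% 2L, (wd[2] - 1L) %/% 2L,
                       (wd[3] - 1L) %/% 2L)
  ymat <- cols %*% matrix(W, ncol = wd[5])
  add_bias_cpp(ymat, b)
  y <- ymat
  dim(y) <- c(d[1], d[2], d[3], d[4], wd[5])
  list(y = y,
       cache = if (keep) list(cols = cols, W = W, d = d, wd = wd) else NULL)
}

conv3d_bw <- function(cache, dy) {
  d <- cache$d; wd <- cache$wd
  dym <- dy
  dim(dym) <- c(prod(d[1:4]), wd[5])
  wmat <- matrix(cache$W, ncol = wd[5])
  dW <- array(crossprod(cache$cols, dym), dim = wd)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, wmat)
  dx <- col2im3d_cpp(dcols, as.integer(d), wd[1], wd[2], wd[3],
                     (wd[1] - 1L) %/% 2L, (wd[2] - 1L) %/% 2L,
                     (wd[3] - 1L) %/% 2L)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# Batch normalization over all but the trailing channel axis. Running
# statistics use momentum-0.1 updates and drive inference mode.
bn_fw <- function(x, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); nd <- length(d)
  C <- d[nd]
  xm <- x
  dim(xm) <- c(prod(d[-nd]), C)
  if (train) {
    st <- bn_stats_cpp(xm)
    mu <- st$mu
    v <- pmax(st$m2 - mu^2, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  r <- bn_apply_cpp(xm, mu, invstd, gamma, beta)
  y <- r$y
  dim(y) <- d
  list(y = y, state = state,
       cache = list(xhat = r$xhat, invstd = invstd, gamma = gamma, d = d,
                    train = train))
}

bn_bw <- function(cache, dy) {
  d <- cache$d
  dym <- dy
  dim(dym) <- dim(cache$xhat)
  r <- bn_bw_cpp(dym, cache$xhat, cache$gamma, cache$invstd, cache$train)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

relu_fw <- function(x) {
  y <- relu_fw_cpp(x)
  dim(y) <- dim(x)
  list(y = y, cache = y)
}

relu_bw <- function(cache, dy) {
  dx <- relu_bw_cpp(dy, cache)
  dim(dx) <- dim(dy)
  dx
}

# Clamped logistic output: the clamp keeps values strictly inside (0, 1)
# in double precision.
sigmoid_fw <- function(z) {
  z <- pmin(pmax(z, -30), 30)
  1 / (1 + exp(-z))
}

dropout_fw <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- 1 - rate
  m <- (runif(length(x)) < keep) / keep
  dim(m) <- dim(x)
  list(y = x * m, cache = m)
}

dropout_bw <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

# With the channel axis last, channel concatenation is plain vector
# concatenation and the split is a contiguous cut.
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  out <- c(a, b)
  dim(out) <- c(da[-nd], da[nd] + db[nd])
  out
}

split_channels <- function(x, c1) {
  d <- dim(x); nd <- length(d)
  m <- prod(d[-nd])
  a <- x[seq_len(m * c1)]
  dim(a) <- c(d[-nd], c1)
  b <- x[(m * c1 + 1L):length(x)]
  dim(b) <- c(d[-nd], d[nd] - c1)
  list(a = a, b = b)
}

# Per-sample composite soft loss over a batch (sample axis next-to-last,
# single channel); returns the mean loss and its gradient with respect to
# the probability map.
soft_loss_batch <- function(p, g, eps = 1e-6) {
  d <- dim(p); B <- d[length(d) - 1L]
  pm <- matrix(p, ncol = B); gm <- matrix(g, ncol = B)
  i <- colSums(pm * gm)
  sp <- colSums(pm); sg <- colSums(gm)
  s <- sp + sg
  u <- s - i
  loss <- 2 - (i + eps) / (u + eps) - (2 * i + eps) / (s + eps)
  # d/dp of -(I+e)/(U+e): -(g*(U+e) - (I+e)*(1-g)) / (U+e)^2
  # d/dp of -(2I+e)/(S+e): -(2g*(S+e) - (2I+e)) / (S+e)^2
  ue <- u + eps; se <- s + eps; ie <- i + eps
  t1 <- sweep(sweep(gm, 2, ue + ie, "*"), 2, ie, "-")
  dp1 <- -sweep(t1, 2, ue^2, "/")
  t2 <- sweep(sweep(gm, 2, 2 * se, "*"), 2, 2 * i + eps, "-")
  dp2 <- -sweep(t2, 2, se^2, "/")
  dp <- (dp1 + dp2) / B
  dim(dp) <- d
  # soft-DSC is reported from counts pooled over the batch: a sample with an
  # empty mask then contributes only its (small) false-positive mass instead
  # of zeroing its own per-sample ratio.
  list(loss = mean(loss), per_sample = loss, dp = dp,
       i_tot = sum(i), s_tot = sum(s),
       soft_dsc = (2 * sum(i) + eps) / (sum(s) + eps))
}

clip_grad_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    grads <- lapply(grads, function(g) g * sc)
  }
  grads
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
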