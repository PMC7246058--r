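# Independent brute-force oracles used to validate the package's fast paths.

# Connected components of a binary 3D array under 26-connectivity, by
# breadth-first flood fill on a zero-padded grid.
cc_count_26 <- function(mask) {
  d <- dim(mask)
  pz <- d[1] + 2L; py <- d[2] + 2L; px <- d[3] + 2L
  pad <- array(FALSE, c(pz, py, px))
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask != 0
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  loff <- offs[, 1] + pz * offs[, 2] + pz * py * offs[, 3]
  seen <- logical(length(pad))
  ncomp <- 0L
  for (start in which(pad)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier) > 0) {
      nb <- unique(as.vector(outer(frontier, loff, "+")))
      nb <- nb[pad[nb] & !seen[nb]]
      seen[nb] <- TRUE
      frontier <- nb
    }
  }
  ncomp
}

# Point-in-polygon by crossing count, edge-inclusive; one point at a time.
pip_naive <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    x1 <- xy[i, 1]; y1 <- xy[i, 2]; x2 <- xy[j, 1]; y2 <- xy[j, 2]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) < 1e-9 * max(1, abs(x2 - x1), abs(y2 - y1)) &&
        px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9)
      return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xin <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xin) inside <- !inside
    }
  }
  inside
}

# Random simple (star-shaped) polygon: jittered radii at sorted angles.
random_polygon <- function(nv, cx, cy, rmin, rmax) {
  ang <- sort(runif(nv, 0, 2 * pi))
  r <- runif(nv, rmin, rmax)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# Exact two-sided signed-rank p by full sign enumeration.
wilcoxon_enum <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mean(abs(vs - mu) >= abs(v - mu) - 1e-9)
}

# Per-voxel majority vote by explicit loops.
naive_vote <- function(masks) {
  d <- dim(masks[[1]])
  out <- array(0L, d)
  k <- length(masks)
  for (z in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (x in seq_len(d[3])) {
        votes <- sum(vapply(masks, function(m) m[z, y, x], numeric(1)))
        out[z, y, x] <- as.integer(votes > k / 2)
      }
  out
}

# Small jittered phantom cohort shared across training tests.
tiny_cohort <- function(n, grid = c(8L, 16L, 16L), seed = 5L) {
  cases <- generate_cohort(n, phantom_config(grid_shape = grid), seed = seed)
  names(cases) <- vapply(cases, `[[`, character(1), "case_id")
  cases
}
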