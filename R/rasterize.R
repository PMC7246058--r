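# Contour rasterization and geometric normalization.

# Even-odd point-in-polygon over a grid of pixel centres. Points exactly on
# a polygon edge count as inside. xs/ys are the pixel-centre coordinates of
# the columns/rows in patient mm.
polygon_raster <- function(xy, xs, ys) {
  nv <- nrow(xy)
  X <- length(xs); Y <- length(ys)
  PX <- matrix(xs, Y, X, byrow = TRUE)
  PY <- matrix(ys, Y, X)
  cnt <- matrix(0L, Y, X)
  onedge <- matrix(FALSE, Y, X)
  eps <- 1e-9 * max(1, diff(range(xy)))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    x1 <- xy[i, 1]; y1 <- xy[i, 2]; x2 <- xy[j, 1]; y2 <- xy[j, 2]
    if (y1 != y2) {
      crossing <- ((y1 > PY) != (y2 > PY)) &
        (PX < x1 + (PY - y1) * (x2 - x1) / (y2 - y1))
      cnt <- cnt + crossing
    }
    # distance-free collinearity + bounding-box test for "on the edge"
    d <- abs((x2 - x1) * (PY - y1) - (y2 - y1) * (PX - x1))
    seg <- d <= eps * max(abs(x2 - x1), abs(y2 - y1), 1) &
      PX >= min(x1, x2) - eps & PX <= max(x1, x2) + eps &
      PY >= min(y1, y2) - eps & PY <= max(y1, y2) + eps
    onedge <- onedge | seg
  }
  (cnt %% 2L == 1L) | onedge
}

#' Rasterize structure-set contours onto a CT grid
#'
#' Each planar contour is matched to the CT slice whose patient z is nearest
#' (within half the slice gap) and filled by the even-odd rule evaluated at
#' pixel centres, with points exactly on an edge counting as inside.
#' Multiple contours of one structure on the same slice combine by even-odd
#' parity, so inner contours carve holes; the listed structures are then
#' merged by union — e.g. the right and left lungs into one whole-lung mask.
#'
#' @param ss a [read_rtstruct()] result.
#' @param names structure names to merge.
#' @param ct a [read_ct_series()] result supplying the voxel grid.
#' @param tol z-matching tolerance in mm (default: half the slice gap).
#' @return A `mask_volume`: list with binary `voxels` aligned to `ct` and
#'   `provenance` (the merged structure names).
#' @export
rasterize <- function(ss, names, ct, tol = NULL) {
  stopifnot(inherits(ss, "structure_set"), inherits(ct, "ct_volume"))
  missing <- setdiff(names, names(ss$structures))
  if (length(missing) > 0)
    stop0("structures not present: ", paste(missing, collapse = ", "))
  zs <- ct$slice_positions
  tol <- tol %||% if (length(zs) > 1) min(diff(zs)) / 2 else 0.5
  d <- dim(ct$voxels)
  xs <- ct$origin[1] + (seq_len(d[3]) - 1) * ct$pixel_spacing[2]
  ys <- ct$origin[2] + (seq_len(d[2]) - 1) * ct$pixel_spacing[1]
  out <- array(FALSE, d)
  for (nm in names) {
    parity <- array(0L, d)
    for (ct_i in seq_along(ss$structures[[nm]])) {
      contour <- ss$structures[[nm]][[ct_i]]
      dz <- abs(zs - contour$z)
      zi <- which.min(dz)
      if (dz[zi] > tol)
        stop0("contour ", ct_i, " of '", nm, "' at z=", contour$z,
              " mm matches no CT slice within ", signif(tol, 3), " mm")
      parity[zi, , ] <- parity[zi, , ] + polygon_raster(contour$xy, xs, ys)
    }
    out <- out | (parity %% 2L == 1L)
  }
  structure(list(voxels = array(as.integer(out), d), provenance = names),
            class = "mask_volume")
}

mask_voxels <- function(x) {
  if (inherits(x, "mask_volume")) x$voxels else x
}

#' Voxelwise set algebra on masks
#'
#' @param a,b binary arrays or `mask_volume`s of equal shape.
#' @param op one of `"union"`, `"difference"` (a minus b), `"intersection"`.
#' @return Object of the same kind as `a` with the combined voxels.
#' @export
boolean_combine <- function(a, b, op = c("union", "difference", "intersection")) {
  op <- match.arg(op)
  av <- mask_voxels(a); bv <- mask_voxels(b)
  if (!identical(dim(av), dim(bv))) stop0("mask shapes differ")
  out <- switch(op,
                union = (av != 0) | (bv != 0),
                difference = (av != 0) & !(bv != 0),
                intersection = (av != 0) & (bv != 0))
  out <- array(as.integer(out), dim(av))
  if (inherits(a, "mask_volume"))
    structure(list(voxels = out,
                   provenance = c(a$provenance, op, b$provenance)),
              class = "mask_volume")
  else out
}

# In-plane resize of one slice. Intensities: block averaging when the source
# is an integer multiple of the target (the 512 -> 128 case), bilinear
# sampling otherwise. Masks: nearest neighbour, so labels stay binary.
resize_plane <- function(m, th, tw, method = c("intensity", "nearest")) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  if (H == th && W == tw) return(m)
  if (method == "nearest") {
    ri <- pmin(pmax(round((seq_len(th) - 0.5) * H / th + 0.5), 1), H)
    ci <- pmin(pmax(round((seq_len(tw) - 0.5) * W / tw + 0.5), 1), W)
    return(m[ri, ci, drop = FALSE])
  }
  if (H %% th == 0 && W %% tw == 0) {
    fh <- H %/% th; fw <- W %/% tw
    a <- colMeans(array(m, c(fh, th * W)))        # average block rows
    a <- array(a, c(th, fw, tw))
    return(apply(a, c(1, 3), mean))               # average block cols
  }
  wmat <- function(S, T) {
    w <- matrix(0, T, S)
    for (t in seq_len(T)) {
      s <- (t - 0.5) * S / T + 0.5
      s0 <- floor(s)
      fr <- s - s0
      s0 <- min(max(s0, 1), S)
      s1 <- min(s0 + 1, S)
      w[t, s0] <- w[t, s0] + (1 - fr)
      w[t, s1] <- w[t, s1] + fr
    }
    w
  }
  wmat(H, th) %*% m %*% t(wmat(W, tw))
}

#' Normalize a case to the fixed network geometry
#'
#' Resizes every slice in-plane to the target (area averaging for the
#' intensity image, nearest neighbour for the mask so it stays binary),
#' forces the slice count to the target by uniform index sampling when the
#' stack is longer and symmetric zero padding when shorter, and windows the
#' intensities linearly to \[0, 255\] (default window: the per-case min-max
#' range).
#'
#' @param volume numeric array (slices, rows, cols).
#' @param mask binary array or `mask_volume` aligned with `volume`, or
#'   `NULL`.
#' @param target output geometry (slices, rows, cols), default 32 x 128 x
#'   128.
#' @param window optional `c(low, high)` intensity window.
#' @return List with integer `volume` (values 0-255), binary `mask` (or
#'   `NULL`) and the `window` used.
#' @export
normalize_case <- function(volume, mask = NULL, target = c(32L, 128L, 128L),
                           window = NULL) {
  mk <- if (!is.null(mask)) mask_voxels(mask)
  if (!is.null(mk) && !identical(dim(mk), dim(volume)))
    stop0("volume and mask are not aligned")
  d <- dim(volume)
  TZ <- target[1]; TH <- target[2]; TW <- target[3]
  # slice-count normalization first (cheaper before the in-plane resize)
  if (d[1] > TZ) {
    zi <- round((seq_len(TZ) - 1) * (d[1] - 1) / (TZ - 1)) + 1
    volume <- volume[zi, , , drop = FALSE]
    if (!is.null(mk)) mk <- mk[zi, , , drop = FALSE]
  } else if (d[1] < TZ) {
    before <- (TZ - d[1]) %/% 2L
    pad <- function(a) {
      out <- array(0, c(TZ, dim(a)[2], dim(a)[3]))
      out[before + seq_len(dim(a)[1]), , ] <- a
      out
    }
    volume <- pad(volume)
    if (!is.null(mk)) mk <- pad(mk)
  }
  vout <- array(0, c(TZ, TH, TW))
  mout <- if (!is.null(mk)) array(0L, c(TZ, TH, TW))
  for (z in seq_len(TZ)) {
    vout[z, , ] <- resize_plane(volume[z, , ], TH, TW, "intensity")
    if (!is.null(mk))
      mout[z, , ] <- resize_plane(mk[z, , ], TH, TW, "nearest")
  }
  w <- window %||% range(vout)
  if (w[2] > w[1]) {
    vout <- (pmin(pmax(vout, w[1]), w[2]) - w[1]) / (w[2] - w[1]) * 255
  } else {
    vout[] <- 0
  }
  vout <- round(vout)
  storage.mode(vout) <- "integer"
  if (!is.null(mout)) {
    storage.mode(mout) <- "integer"
    if (!any(mout != 0)) warning("mask is empty after normalization")
  }
  list(volume = vout, mask = mout, window = w)
}
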