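#' Configuration for a synthetic thorax phantom
#'
#' Describes a voxel grid holding two lung-like ellipsoids and a central
#' trachea-like tube that descends from the top of the volume and bifurcates
#' into two oblique main-bronchus branches. The tube is excluded from the
#' ground-truth lung mask, mirroring the organ-at-risk convention that normal
#' lung is delineated without the trachea and main bronchi. All geometric
#' defaults scale with `grid_shape`, so small grids for fast experiments and
#' the full 32 x 128 x 128 geometry use the same relative anatomy.
#'
#' @param grid_shape integer vector (slices, rows, cols); each component >= 8.
#' @param lung_semiaxes list with `left` and `right` numeric (z, y, x)
#'   ellipsoid semiaxes in voxels.
#' @param lung_centers list with `left` and `right` numeric (z, y, x) centers
#'   in voxel coordinates (1-based).
#' @param tube_radius trachea radius in voxels; `0` disables the tube.
#' @param branch_radius main-bronchus radius in voxels (>= 1 when the tube is
#'   enabled).
#' @param tube_center numeric (y, x) axis position of the trachea.
#' @param tube_z_extent fraction of slices, from the top, that the airway
#'   spans.
#' @param bifurcation_slice slice index where the trachea splits into the two
#'   branches.
#' @param branch_slope lateral displacement, in voxels per slice, of each
#'   branch centre below the bifurcation.
#' @param intensity_levels named numeric: `background`, `soft_tissue`, `lung`,
#'   `tube` grey levels in \[0, 255\]; must be pairwise distinct.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param lung_fraction_band admissible band for the lung voxel fraction of
#'   the grid.
#' @param seed integer seed for the noise stream.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 128L, 128L),
                           lung_semiaxes = NULL,
                           lung_centers = NULL,
                           tube_radius = NULL,
                           branch_radius = NULL,
                           tube_center = NULL,
                           tube_z_extent = 0.55,
                           bifurcation_slice = NULL,
                           branch_slope = NULL,
                           intensity_levels = c(background = 0, soft_tissue = 120,
                                                lung = 64, tube = 200),
                           noise_sd = 6,
                           lung_fraction_band = c(0.05, 0.5),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop0("grid_shape must be three voxel counts, each >= 8")
  Z <- grid_shape[1]; Y <- grid_shape[2]; X <- grid_shape[3]

  # z semiaxis fraction leaves headroom for the +/-15% cohort jitter:
  # 0.53 + 1.15*0.34 + 0.15*0.34 < 1 on every grid
  lung_semiaxes <- lung_semiaxes %||% list(
    left  = c(0.34 * Z, 0.3125 * Y, 0.171875 * X),
    right = c(0.34 * Z, 0.3125 * Y, 0.171875 * X))
  lung_centers <- lung_centers %||% list(
    left  = c(0.53 * Z, 0.52 * Y, 0.3125 * X),
    right = c(0.53 * Z, 0.52 * Y, 0.6875 * X))
  tube_radius <- tube_radius %||% max(1, round(0.0234 * X))
  branch_radius <- branch_radius %||% max(1, round(0.7 * tube_radius))
  tube_center <- tube_center %||% c(0.469 * Y, 0.5 * X)
  bifurcation_slice <- bifurcation_slice %||% max(2L, round(0.375 * Z))
  branch_slope <- branch_slope %||% max(0.6, 0.0195 * X)

  cfg <- structure(list(
    grid_shape = grid_shape,
    lung_semiaxes = lapply(lung_semiaxes, as.numeric),
    lung_centers = lapply(lung_centers, as.numeric),
    tube_radius = as.numeric(tube_radius),
    branch_radius = as.numeric(branch_radius),
    tube_center = as.numeric(tube_center),
    tube_z_extent = as.numeric(tube_z_extent),
    bifurcation_slice = as.integer(bifurcation_slice),
    branch_slope = as.numeric(branch_slope),
    intensity_levels = intensity_levels,
    noise_sd = as.numeric(noise_sd),
    lung_fraction_band = as.numeric(lung_fraction_band),
    seed = as.integer(seed)), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  g <- cfg$grid_shape
  if (anyDuplicated(cfg$intensity_levels))
    stop0("intensity levels must be pairwise distinct")
  if (any(cfg$intensity_levels < 0) || any(cfg$intensity_levels > 255))
    stop0("intensity levels must lie in [0, 255]")
  if (cfg$tube_radius < 0)
    stop0("tube_radius must be >= 0 (0 disables the tube)")
  if (cfg$tube_radius > 0 && cfg$branch_radius < 1)
    stop0("branch_radius must be >= 1 when the tube is enabled")
  for (side in c("left", "right")) {
    ctr <- cfg$lung_centers[[side]]
    ax <- cfg$lung_semiaxes[[side]]
    if (length(ctr) != 3L || length(ax) != 3L || any(ax <= 0))
      stop0("lung geometry for '", side, "' must be three positive semiaxes ",
            "and a three-component centre")
    # voxel i covers [i - 0.5, i + 0.5], so the grid spans [0.5, dim + 0.5]
    if (any(ctr - ax < 0.5) || any(ctr + ax > g + 0.5))
      stop0("lung ellipsoid '", side, "' does not fit inside the grid")
  }
  if (cfg$tube_radius > 0) {
    zmax <- round(cfg$tube_z_extent * g[1])
    if (zmax < cfg$bifurcation_slice)
      stop0("tube_z_extent ends above the bifurcation slice")
    reach <- cfg$tube_radius +
      cfg$branch_radius + cfg$branch_slope * (zmax - cfg$bifurcation_slice)
    if (cfg$tube_center[2] - reach < 1 || cfg$tube_center[2] + reach > g[3] ||
        cfg$tube_center[1] - cfg$tube_radius < 1 ||
        cfg$tube_center[1] + cfg$tube_radius > g[2])
      stop0("airway tube extends outside the grid")
  }
  invisible(cfg)
}

ellipsoid_mask <- function(grid_shape, center, semiaxes) {
  Z <- grid_shape[1]; Y <- grid_shape[2]; X <- grid_shape[3]
  dz2 <- ((seq_len(Z) - center[1]) / semiaxes[1])^2
  dy2 <- ((seq_len(Y) - center[2]) / semiaxes[2])^2
  dx2 <- ((seq_len(X) - center[3]) / semiaxes[3])^2
  outer(outer(dz2, dy2, "+"), dx2, "+") <= 1
}

airway_mask <- function(cfg) {
  g <- cfg$grid_shape
  tube <- array(FALSE, g)
  if (cfg$tube_radius == 0) return(tube)
  zmax <- min(g[1], round(cfg$tube_z_extent * g[1]))
  ys <- seq_len(g[2]); xs <- seq_len(g[3])
  disk <- function(cy, cx, r)
    outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  for (z in seq_len(zmax)) {
    if (z <= cfg$bifurcation_slice) {
      tube[z, , ] <- disk(cfg$tube_center[1], cfg$tube_center[2], cfg$tube_radius)
    } else {
      d <- (z - cfg$bifurcation_slice) * cfg$branch_slope
      tube[z, , ] <- disk(cfg$tube_center[1], cfg$tube_center[2] - d, cfg$branch_radius) |
                     disk(cfg$tube_center[1], cfg$tube_center[2] + d, cfg$branch_radius)
    }
  }
  tube
}

#' Generate one synthetic thorax phantom
#'
#' Builds an 8-bit CT-like volume (background, a soft-tissue body ellipsoid,
#' two dark lung ellipsoids, a bright airway tube) plus the ground-truth lung
#' mask with the airway carved out. Given the same configuration (including
#' its seed) the output is bit-identical across calls.
#'
#' @param config a [phantom_config()].
#' @return A `phantom_case`: list with integer `volume` (slices x rows x cols,
#'   values 0-255), binary `mask` (lung excluding the airway), binary
#'   `tube_mask`, the `config`, and the `seed` used for the noise stream.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  g <- config$grid_shape
  lev <- config$intensity_levels

  body <- ellipsoid_mask(g, c(0.53 * g[1], 0.5 * g[2], 0.5 * g[3]),
                         c(0.5 * g[1], 0.44 * g[2], 0.47 * g[3]))
  lung <- ellipsoid_mask(g, config$lung_centers$left, config$lung_semiaxes$left) |
          ellipsoid_mask(g, config$lung_centers$right, config$lung_semiaxes$right)
  tube <- airway_mask(config)

  vol <- array(lev[["background"]], g)
  vol[body] <- lev[["soft_tissue"]]
  vol[lung] <- lev[["lung"]]
  vol[tube] <- lev[["tube"]]

  mask <- lung & !tube

  if (config$noise_sd > 0) {
    set.seed(config$seed)
    vol <- vol + rnorm(length(vol), 0, config$noise_sd)
  }
  vol <- round(pmin(pmax(vol, 0), 255))
  storage.mode(vol) <- "integer"

  if (!any(mask)) stop0("phantom mask is empty; check the configuration")
  frac <- mean(mask)
  band <- config$lung_fraction_band
  if (frac < band[1] || frac > band[2])
    stop0(sprintf("lung voxel fraction %.3f outside the configured band [%g, %g]",
                  frac, band[1], band[2]))

  structure(list(volume = vol,
                 mask = array(as.integer(mask), g),
                 tube_mask = array(as.integer(tube), g),
                 config = config,
                 seed = config$seed),
            class = "phantom_case")
}

#' Generate a cohort of jittered phantoms
#'
#' Draws `n` phantoms whose lung semiaxes are scaled by uniform factors in
#' \[0.85, 1.15\] and whose lung centres are displaced by up to 15% of the
#' corresponding semiaxis, so cases differ in size and position while every
#' case keeps its lungs inside the grid. Per-case noise seeds are derived
#' deterministically from `seed`.
#'
#' @param n number of cases (>= 1).
#' @param base_config a [phantom_config()] supplying base geometry.
#' @param seed integer seed driving both the jitter and the per-case seeds.
#' @return List of `phantom_case` objects; each carries a `case_id`.
#' @export
generate_cohort <- function(n, base_config = phantom_config(), seed = 1L) {
  if (n < 1) stop0("n must be >= 1")
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max, n)
  jit <- lapply(seq_len(n), function(i)
    list(scale = lapply(c(left = "left", right = "right"),
                        function(s) runif(3, 0.85, 1.15)),
         shift = lapply(c(left = "left", right = "right"),
                        function(s) runif(3, -0.15, 0.15))))
  lapply(seq_len(n), function(i) {
    cfg <- base_config
    for (side in c("left", "right")) {
      ax <- cfg$lung_semiaxes[[side]] * jit[[i]]$scale[[side]]
      cfg$lung_centers[[side]] <- cfg$lung_centers[[side]] +
        jit[[i]]$shift[[side]] * cfg$lung_semiaxes[[side]]
      cfg$lung_semiaxes[[side]] <- ax
    }
    cfg$seed <- case_seeds[i]
    case <- generate_phantom(cfg)
    case$case_id <- sprintf("case_%03d", i)
    case
  })
}

#' Lung voxel fraction of a phantom or mask
#' @param x a `phantom_case` or a binary array.
#' @return Fraction of grid voxels labelled lung.
#' @export
lung_fraction <- function(x) {
  m <- if (inherits(x, "phantom_case")) x$mask else x
  mean(m != 0)
}
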