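#' Write a case as a directory of PNG slices
#'
#' Stores the volume as 8-bit grayscale PNGs (`img_###.png`) and the mask as
#' binary PNGs with lung voxels white (255) and everything else black
#' (`msk_###.png`), plus a plain-text `meta.txt` sidecar. The representation
#' is lossless: [read_png_stack()] recovers the arrays exactly.
#'
#' @param case list with integer `volume` (slices x rows x cols, 0-255),
#'   binary `mask` of the same shape (may be `NULL`), and optional named
#'   `meta` values; a `phantom_case` works directly.
#' @param directory output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_png_stack <- function(case, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  vol <- case$volume
  if (is.null(vol)) stop0("case has no volume")
  if (any(vol < 0) || any(vol > 255)) stop0("volume values must lie in [0, 255]")
  Z <- dim(vol)[1]
  for (z in seq_len(Z))
    png::writePNG(vol[z, , ] / 255,
                  file.path(directory, sprintf("img_%03d.png", z - 1L)))
  if (!is.null(case$mask)) {
    m <- case$mask
    if (!all(m %in% c(0, 1))) stop0("mask values must be 0/1")
    if (!identical(dim(m), dim(vol))) stop0("mask and volume shapes differ")
    for (z in seq_len(Z))
      png::writePNG(m[z, , ] * 1.0,
                    file.path(directory, sprintf("msk_%03d.png", z - 1L)))
  }
  meta <- case$meta
  if (is.null(meta) && !is.null(case$seed)) meta <- list(seed = case$seed)
  if (!is.null(meta)) {
    lines <- vapply(names(meta),
                    function(k) paste0(k, "=", paste(meta[[k]], collapse = ",")),
                    character(1))
    writeLines(lines, file.path(directory, "meta.txt"))
  }
  invisible(directory)
}

read_png_plane <- function(path) {
  p <- png::readPNG(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate grey+alpha
  round(p * 255)
}

#' Read a case back from a directory of PNG slices
#'
#' @param directory directory produced by [write_png_stack()].
#' @return List with integer `volume`, binary `mask` (or `NULL` when no mask
#'   slices are present) and `meta` (named character values from `meta.txt`).
#' @export
read_png_stack <- function(directory) {
  imgs <- sort(list.files(directory, pattern = "^img_\\d+\\.png$", full.names = TRUE))
  msks <- sort(list.files(directory, pattern = "^msk_\\d+\\.png$", full.names = TRUE))
  if (length(imgs) == 0L) stop0("no img_###.png slices found in ", directory)
  first <- read_png_plane(imgs[1])
  vol <- array(0L, c(length(imgs), nrow(first), ncol(first)))
  for (z in seq_along(imgs)) vol[z, , ] <- as.integer(read_png_plane(imgs[z]))
  mask <- NULL
  if (length(msks) > 0L) {
    if (length(msks) != length(imgs))
      stop0("mask slice count does not match image slice count")
    mask <- array(0L, dim(vol))
    for (z in seq_along(msks)) {
      m <- read_png_plane(msks[z])
      if (!all(m %in% c(0, 255)))
        stop0("mask PNG ", basename(msks[z]), " contains values other than 0/255")
      mask[z, , ] <- as.integer(m / 255)
    }
  }
  meta <- NULL
  mf <- file.path(directory, "meta.txt")
  if (file.exists(mf)) {
    kv <- strsplit(readLines(mf), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                            vapply(kv, `[`, character(1), 1))
  }
  list(volume = vol, mask = mask, meta = meta)
}

#' Write a cohort of cases as numbered PNG case directories
#' @param cases list of cases (e.g. from [generate_cohort()]).
#' @param directory parent output directory.
#' @return Character vector of per-case directories, invisibly.
#' @export
write_case_dirs <- function(cases, directory) {
  dirs <- character(length(cases))
  for (i in seq_along(cases)) {
    id <- cases[[i]]$case_id %||% sprintf("case_%03d", i)
    dirs[i] <- file.path(directory, id)
    case <- cases[[i]]
    case$meta <- list(case_id = id, seed = case$seed %||% NA)
    write_png_stack(case, dirs[i])
  }
  invisible(dirs)
}

#' Read all PNG case directories under a parent directory
#' @param directory parent directory containing one subdirectory per case.
#' @return Named list of cases (volume, mask, meta), sorted by directory name.
#' @export
read_case_dirs <- function(directory) {
  subs <- sort(list.dirs(directory, recursive = FALSE))
  subs <- subs[vapply(subs, function(d)
    length(list.files(d, pattern = "^img_\\d+\\.png$")) > 0, logical(1))]
  if (length(subs) == 0L) stop0("no PNG case directories under ", directory)
  stats::setNames(lapply(subs, read_png_stack), basename(subs))
}
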