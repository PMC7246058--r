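# Minimal DICOM reader: explicit and implicit VR little endian, nested
# sequences with defined or undefined lengths — the subset needed for CT
# series and RT Structure Sets. Values are decoded by VR; sequences become
# lists of nested datasets keyed "GGGG,EEEE".

dcm_u16 <- function(b, p) as.integer(b[p]) + 256L * as.integer(b[p + 1])
dcm_u32 <- function(b, p)
  sum(as.numeric(b[p:(p + 3)]) * c(1, 256, 65536, 16777216))

dcm_implicit_vr <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0020,000D" = "UI", "0020,000E" = "UI", "0020,0032" = "DS",
  "0020,0037" = "DS", "0020,1041" = "DS",
  "0028,0002" = "US", "0028,0010" = "US", "0028,0011" = "US",
  "0028,0030" = "DS", "0028,0100" = "US", "0028,0101" = "US",
  "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS",
  "3006,0020" = "SQ", "3006,0022" = "IS", "3006,0026" = "LO",
  "3006,0039" = "SQ", "3006,0040" = "SQ", "3006,0042" = "CS",
  "3006,0046" = "IS", "3006,0050" = "DS", "3006,0084" = "IS",
  "7FE0,0010" = "OW")

dcm_str <- function(raw) {
  raw <- raw[raw != as.raw(0)]  # UI values are NUL-padded
  sub("[ ]+$", "", rawToChar(raw))
}

dcm_decode <- function(vr, raw) {
  n <- length(raw)
  switch(vr,
    US = readBin(raw, "integer", n = n / 2, size = 2, endian = "little",
                 signed = FALSE),
    SS = readBin(raw, "integer", n = n / 2, size = 2, endian = "little"),
    UL = ,
    SL = readBin(raw, "integer", n = n / 4, size = 4, endian = "little"),
    FL = readBin(raw, "double", n = n / 4, size = 4, endian = "little"),
    FD = readBin(raw, "double", n = n / 8, size = 8, endian = "little"),
    DS = ,
    IS = as.numeric(strsplit(dcm_str(raw), "\\", fixed = TRUE)[[1]]),
    OW = ,
    OB = ,
    UN = raw,
    dcm_str(raw))
}

# Parse elements in [pos, end); returns list(elems, pos). Stops early at an
# item-delimitation tag (FFFE,E00D), consuming it.
dcm_parse_dataset <- function(b, pos, end, explicit) {
  elems <- list()
  while (pos < end) {
    g <- dcm_u16(b, pos); e <- dcm_u16(b, pos + 2)
    if (g == 0xFFFE) {
      if (e == 0xE00D) return(list(elems = elems, pos = pos + 8))
      stop0("unexpected item tag in dataset")
    }
    if (explicit) {
      vr <- rawToChar(b[(pos + 4):(pos + 5)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- dcm_u32(b, pos + 8); dpos <- pos + 12
      } else {
        len <- dcm_u16(b, pos + 6); dpos <- pos + 8
      }
    } else {
      len <- dcm_u32(b, pos + 4); dpos <- pos + 8
      key0 <- sprintf("%04X,%04X", g, e)
      vr <- if (key0 %in% names(dcm_implicit_vr)) dcm_implicit_vr[[key0]]
        else "UN"
      if (len == 4294967295) vr <- "SQ"
    }
    key <- sprintf("%04X,%04X", g, e)
    if (vr == "SQ") {
      sq <- dcm_parse_sq(b, dpos, len, explicit)
      elems[[key]] <- sq$items
      pos <- sq$pos
    } else {
      if (len == 4294967295)
        stop0("undefined length outside a sequence is not supported")
      elems[[key]] <- if (len > 0) dcm_decode(vr, b[dpos:(dpos + len - 1)])
        else NULL
      pos <- dpos + len
    }
  }
  list(elems = elems, pos = pos)
}

dcm_parse_sq <- function(b, pos, len, explicit) {
  items <- list()
  end <- if (len == 4294967295) length(b) + 1 else pos + len
  while (pos < end) {
    g <- dcm_u16(b, pos); e <- dcm_u16(b, pos + 2)
    ilen <- dcm_u32(b, pos + 4)
    pos <- pos + 8
    if (g == 0xFFFE && e == 0xE0DD) break       # sequence delimiter
    if (!(g == 0xFFFE && e == 0xE000)) stop0("malformed sequence item")
    if (ilen == 4294967295) {
      r <- dcm_parse_dataset(b, pos, length(b) + 1, explicit)
    } else {
      r <- dcm_parse_dataset(b, pos, pos + ilen, explicit)
    }
    items[[length(items) + 1L]] <- r$elems
    pos <- r$pos
  }
  list(items = items, pos = pos)
}

#' Read a single DICOM file
#'
#' Supports explicit and implicit VR little endian transfer syntaxes with
#' nested sequences. Returns the decoded data set as a named list keyed by
#' `"GGGG,EEEE"` tag; sequence values are lists of nested datasets.
#'
#' @param path DICOM file path.
#' @return Named list of decoded elements.
#' @export
read_dicom <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  if (length(b) < 140 || rawToChar(b[129:132]) != "DICM")
    stop0(path, " is not a DICOM part-10 file")
  pos <- 133
  ts <- "1.2.840.10008.1.2.1"
  # file meta group (0002,*) is always explicit VR little endian
  while (pos < length(b) && dcm_u16(b, pos) == 2L) {
    vr <- rawToChar(b[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- dcm_u32(b, pos + 8); dpos <- pos + 12
    } else {
      len <- dcm_u16(b, pos + 6); dpos <- pos + 8
    }
    if (dcm_u16(b, pos + 2) == 0x0010)
      ts <- dcm_str(b[dpos:(dpos + len - 1)])
    pos <- dpos + len
  }
  explicit <- ts != "1.2.840.10008.1.2"
  dcm_parse_dataset(b, pos, length(b) + 1, explicit)$elems
}

#' Read a DICOM CT series from a directory
#'
#' All slices must belong to one series (mixed SeriesInstanceUIDs are an
#' error). Slices are sorted by the patient z of ImagePositionPatient and
#' the rescale slope/intercept is applied to the stored pixel values.
#'
#' @param directory directory holding the per-slice DICOM files.
#' @return A `ct_volume`: list with numeric `voxels` (slices, rows, cols),
#'   `pixel_spacing` (row, col) mm, sorted `slice_positions` mm, `origin`
#'   (ImagePositionPatient of the first sorted slice) and `rescaled = TRUE`.
#' @export
read_ct_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  dsets <- lapply(files, read_dicom)
  has_px <- vapply(dsets, function(d) !is.null(d[["7FE0,0010"]]), logical(1))
  dsets <- dsets[has_px]
  if (length(dsets) == 0L) stop0("no image slices found in ", directory)
  uids <- vapply(dsets, function(d) d[["0020,000E"]] %||% "", character(1))
  if (length(unique(uids)) != 1L)
    stop0("directory mixes more than one series (", length(unique(uids)),
          " SeriesInstanceUIDs)")
  need <- function(d, key, what)
    d[[key]] %||% stop0("missing ", what, " tag (", key, ")")
  rows <- vapply(dsets, function(d) as.integer(need(d, "0028,0010", "Rows")),
                 integer(1))
  cols <- vapply(dsets, function(d) as.integer(need(d, "0028,0011", "Columns")),
                 integer(1))
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L)
    stop0("slices disagree on matrix size")
  spac <- lapply(dsets, function(d) need(d, "0028,0030", "PixelSpacing"))
  if (length(unique(vapply(spac, paste, character(1), collapse = ","))) != 1L)
    stop0("slices disagree on pixel spacing")
  ipp <- lapply(dsets, function(d) need(d, "0020,0032", "ImagePositionPatient"))
  z <- vapply(ipp, `[`, numeric(1), 3)
  ord <- order(z)
  if (any(diff(z[ord]) <= 0))
    stop0("slice positions are not strictly monotonic")
  Z <- length(dsets); R <- rows[1]; C <- cols[1]
  vox <- array(0, c(Z, R, C))
  for (k in seq_len(Z)) {
    d <- dsets[[ord[k]]]
    bits <- (d[["0028,0100"]] %||% 16L)[1]
    signed <- (d[["0028,0103"]] %||% 0L)[1] == 1L
    raw <- d[["7FE0,0010"]]
    vals <- readBin(raw, "integer", n = length(raw) %/% (bits %/% 8L),
                    size = bits %/% 8L, endian = "little", signed = signed)
    slope <- (d[["0028,1053"]] %||% 1)[1]
    inter <- (d[["0028,1052"]] %||% 0)[1]
    vox[k, , ] <- matrix(slope * vals + inter, nrow = R, byrow = TRUE)
  }
  structure(list(voxels = vox, pixel_spacing = spac[[1]][1:2],
                 slice_positions = z[ord], origin = ipp[[ord[1]]],
                 rescaled = TRUE),
            class = "ct_volume")
}

#' Read a DICOM RT Structure Set
#'
#' Collects, per named structure, the planar contours as (x, y) vertex
#' matrices in patient millimetres with their slice z.
#'
#' @param path RTSTRUCT DICOM file.
#' @return A `structure_set`: list with `structures`, a named list mapping
#'   structure name to a list of contours `list(xy = n x 2 matrix, z = mm)`.
#' @export
read_rtstruct <- function(path) {
  d <- read_dicom(path)
  rois <- d[["3006,0020"]]
  if (is.null(rois)) stop0("no StructureSetROISequence in ", path)
  names_by_num <- stats::setNames(
    vapply(rois, function(it) it[["3006,0026"]] %||% "", character(1)),
    vapply(rois, function(it) as.character(it[["3006,0022"]]), character(1)))
  contours <- d[["3006,0039"]]
  structures <- list()
  for (rc in contours) {
    num <- as.character(rc[["3006,0084"]])
    nm <- names_by_num[[num]] %||% paste0("ROI_", num)
    cs <- lapply(rc[["3006,0040"]] %||% list(), function(ct) {
      pts <- matrix(ct[["3006,0050"]], ncol = 3, byrow = TRUE)
      if (nrow(pts) < 3) stop0("contour of '", nm, "' has fewer than 3 vertices")
      list(xy = pts[, 1:2, drop = FALSE], z = pts[1, 3])
    })
    structures[[nm]] <- c(structures[[nm]] %||% list(), cs)
  }
  structure(list(structures = structures), class = "structure_set")
}
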