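# Minimal DICOM writer (explicit VR little endian) used to build CT and
# RTSTRUCT fixtures programmatically at test time.

dcm_raw_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
dcm_raw_u32 <- function(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))

dcm_pad <- function(bytes, padbyte = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, padbyte) else bytes
}

# value encoding per VR
dcm_value_raw <- function(vr, value) {
  switch(vr,
    US = do.call(c, lapply(as.integer(value), dcm_raw_u16)),
    UL = do.call(c, lapply(as.integer(value), dcm_raw_u32)),
    DS = ,
    IS = dcm_pad(charToRaw(paste(format(value, trim = TRUE, digits = 10),
                                 collapse = "\\"))),
    UI = dcm_pad(charToRaw(as.character(value)), as.raw(0)),
    OW = value,  # already raw
    dcm_pad(charToRaw(as.character(value))))
}

dcm_element <- function(group, elem, vr, value) {
  val <- if (vr == "SQ") value else dcm_value_raw(vr, value)
  tag <- c(dcm_raw_u16(group), dcm_raw_u16(elem))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), dcm_raw_u32(length(val)), val)
  } else {
    c(tag, charToRaw(vr), dcm_raw_u16(length(val)), val)
  }
}

dcm_item <- function(content)
  c(dcm_raw_u16(0xFFFE), dcm_raw_u16(0xE000), dcm_raw_u32(length(content)),
    content)

dcm_write_file <- function(path, dataset_raw) {
  meta <- c(
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset_raw), path)
}

# One CT slice. pixels: rows x cols integer matrix of stored values.
write_ct_slice <- function(path, series_uid, z, pixels,
                           spacing = c(1, 1), origin_xy = c(0, 0),
                           slope = 1, intercept = 0) {
  stored <- as.integer(t(pixels))  # DICOM pixel data is row-major
  pix_raw <- writeBin(stored, raw(), size = 2, endian = "little")
  ds <- c(
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS",
                c(origin_xy[1], origin_xy[2], z)),
    dcm_element(0x0028, 0x0010, "US", nrow(pixels)),
    dcm_element(0x0028, 0x0011, "US", ncol(pixels)),
    dcm_element(0x0028, 0x0030, "DS", spacing),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x0028, 0x1052, "DS", intercept),
    dcm_element(0x0028, 0x1053, "DS", slope),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw))
  dcm_write_file(path, ds)
}

# RTSTRUCT with structures = list(name = list(list(xy = matrix, z = mm), ...))
write_rtstruct_file <- function(path, structures) {
  nms <- names(structures)
  roi_items <- raw(0)
  contour_items <- raw(0)
  for (i in seq_along(structures)) {
    roi_items <- c(roi_items, dcm_item(c(
      dcm_element(0x3006, 0x0022, "IS", i),
      dcm_element(0x3006, 0x0026, "LO", nms[i]))))
    citems <- raw(0)
    for (ct in structures[[i]]) {
      pts <- as.vector(t(cbind(ct$xy, ct$z)))
      citems <- c(citems, dcm_item(c(
        dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", nrow(ct$xy)),
        dcm_element(0x3006, 0x0050, "DS", pts))))
    }
    contour_items <- c(contour_items, dcm_item(c(
      dcm_element(0x3006, 0x0040, "SQ", citems),
      dcm_element(0x3006, 0x0084, "IS", i))))
  }
  ds <- c(
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x3006, 0x0020, "SQ", roi_items),
    dcm_element(0x3006, 0x0039, "SQ", contour_items))
  dcm_write_file(path, ds)
}

# A 3-slice 8x8 CT fixture plus matching simple structures.
write_ct_fixture <- function(dir, uid = "1.2.3.4.5", shuffle = FALSE,
                             slope = 1, intercept = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  zs <- c(0, 3, 6)
  names_on_disk <- if (shuffle) c("c.dcm", "a.dcm", "b.dcm")
    else c("a.dcm", "b.dcm", "c.dcm")
  vols <- list()
  for (k in 1:3) {
    set.seed(100 + k)
    px <- matrix(sample.int(500, 64, replace = TRUE), 8, 8)
    vols[[k]] <- px
    write_ct_slice(file.path(dir, names_on_disk[k]), uid, zs[k], px,
                   slope = slope, intercept = intercept)
  }
  list(zs = zs, vols = vols)
}
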