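# Minimal DICOM codec: explicit-VR little-endian only, axis-aligned RTDOSE
# grids with 32-bit integer pixel data and a DoseGridScaling factor. This is
# deliberately the smallest subset that round-trips the package's own dose
# grids; it is not a general DICOM implementation.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_RTDOSE_STORAGE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_CT_STORAGE     <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPL_ROOT      <- "1.2.826.0.1.3680043.10.9001"

# --- byte-level helpers ------------------------------------------------------

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# one explicit-VR element; OB/OW/SQ/UT/UN use the 12-byte long header
dcm_element <- function(group, element, vr, payload) {
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  head <- c(u16(group), u16(element), charToRaw(vr))
  if (long_form) {
    c(head, as.raw(c(0, 0)), u32(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stop("dcm_element: payload too long for short VR")
    c(head, u16(length(payload)), payload)
  }
}

dcm_str <- function(group, element, vr, s, pad = as.raw(0x20)) {
  dcm_element(group, element, vr, pad_even(charToRaw(s), pad))
}
dcm_ui <- function(group, element, s) dcm_str(group, element, "UI", s, as.raw(0))
dcm_ds <- function(group, element, x) {
  dcm_str(group, element, "DS", paste(formatC(x, format = "fg", digits = 10),
                                      collapse = "\\"))
}
dcm_is <- function(group, element, x) {
  dcm_str(group, element, "IS", paste(as.integer(x), collapse = "\\"))
}
dcm_us <- function(group, element, x) dcm_element(group, element, "US", u16(x))

#' Write a dose grid as a DICOM RTDOSE file
#'
#' Emits an explicit-VR little-endian RTDOSE object with 32-bit integer pixel
#' data. Doses are quantized by `scaling` (`DoseGridScaling`); the default
#' scaling maps the grid maximum to ~2e9 so quantization error is negligible.
#'
#' @param grid a [dose_grid()].
#' @param path output file path.
#' @param scaling dose-grid scaling factor (Gy per stored integer unit), or
#'   `NULL` to derive one from the grid maximum.
#' @param modality DICOM modality string; anything other than `"RTDOSE"` is
#'   only useful for constructing negative test fixtures.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(grid, path, scaling = NULL, modality = "RTDOSE") {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  if (is.null(scaling)) {
    m <- max_dose(grid)
    scaling <- if (m > 0) m / 2e9 else 1e-9
  }
  ints <- as.integer(round(grid$values / scaling))
  sop_uid <- paste0(UID_IMPL_ROOT, ".", paste(sample.int(9999L, 1L)),
                    ".", as.integer(Sys.time()) %% 100000L)
  sop_class <- if (identical(modality, "RTDOSE")) UID_RTDOSE_STORAGE else UID_CT_STORAGE

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_ui(0x0002, 0x0002, sop_class),
    dcm_ui(0x0002, 0x0003, sop_uid),
    dcm_ui(0x0002, 0x0010, UID_EXPLICIT_VR_LE),
    dcm_ui(0x0002, 0x0012, UID_IMPL_ROOT)
  )
  offsets <- (seq_len(d[3]) - 1) * grid$spacing[3]
  body <- c(
    dcm_ui(0x0008, 0x0016, sop_class),
    dcm_ui(0x0008, 0x0018, sop_uid),
    dcm_str(0x0008, 0x0060, "CS", modality),
    dcm_ds(0x0020, 0x0032, grid$origin),
    dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    dcm_us(0x0028, 0x0002, 1),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_is(0x0028, 0x0008, d[3]),
    dcm_us(0x0028, 0x0010, d[2]),             # Rows    = y extent
    dcm_us(0x0028, 0x0011, d[1]),             # Columns = x extent
    dcm_ds(0x0028, 0x0030, grid$spacing[c(2, 1)]),  # row (y) \ column (x)
    dcm_us(0x0028, 0x0100, 32),
    dcm_us(0x0028, 0x0101, 32),
    dcm_us(0x0028, 0x0102, 31),
    dcm_us(0x0028, 0x0103, 0),
    dcm_str(0x3004, 0x0002, "CS", "GY"),
    dcm_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_str(0x3004, 0x000a, "CS", "PLAN"),
    dcm_ds(0x3004, 0x000c, offsets),
    dcm_ds(0x3004, 0x000e, scaling),
    dcm_element(0x7fe0, 0x0010, "OW",
                writeBin(ints, raw(), size = 4, endian = "little"))
  )
  out <- c(raw(128), charToRaw("DICM"),
           dcm_element(0x0002, 0x0000, "UL", u32(length(meta))),
           meta, body)
  writeBin(out, path)
  invisible(path)
}

# sequential explicit-VR parser; returns list keyed "gggg,eeee"
parse_dicom_elements <- function(bytes, start) {
  els <- list()
  i <- start
  n <- length(bytes)
  while (i + 8 <= n) {
    group <- readBin(bytes[i + 0:1], "integer", size = 2, signed = FALSE,
                     endian = "little")
    element <- readBin(bytes[i + 2:3], "integer", size = 2, signed = FALSE,
                       endian = "little")
    vr <- rawToChar(bytes[i + 4:5])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- readBin(bytes[i + 8:11], "integer", size = 4, endian = "little")
      hd <- 12L
    } else {
      len <- readBin(bytes[i + 6:7], "integer", size = 2, signed = FALSE,
                     endian = "little")
      hd <- 8L
    }
    if (len < 0 || i + hd + len - 1 > n)
      stop("read_rtdose: format error, truncated DICOM element", call. = FALSE)
    payload <- if (len > 0) bytes[(i + hd):(i + hd + len - 1)] else raw(0)
    els[[sprintf("%04x,%04x", group, element)]] <- list(vr = vr, bytes = payload)
    i <- i + hd + len
  }
  els
}

el_str <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(e$bytes), useBytes = TRUE))
}
el_nums <- function(els, key) {
  s <- el_str(els, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}
el_us <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$bytes, "integer", size = 2, signed = FALSE, endian = "little")
}

#' Read a DICOM RTDOSE file
#'
#' Supports explicit-VR little-endian RTDOSE objects with axis-aligned
#' orientation, uniform grid-frame offsets, and integer pixel data scaled by
#' `DoseGridScaling` — i.e. what clinical TPS exports and [write_rtdose()]
#' produce. Axis order of the returned array is (x, y, z) in patient
#' coordinates with the origin at the first voxel center.
#'
#' @param path path to an RTDOSE file.
#' @return A [dose_grid()] in Gy.
#' @export
read_rtdose <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("read_rtdose: format error, not a DICOM part-10 file", call. = FALSE)
  els <- parse_dicom_elements(bytes, 133L)
  ts <- el_str(els, "0002,0010")
  if (!is.null(ts) && ts != UID_EXPLICIT_VR_LE)
    stop("read_rtdose: format error, unsupported transfer syntax ", ts, call. = FALSE)
  modality <- el_str(els, "0008,0060")
  if (is.null(modality) || modality != "RTDOSE")
    stop("read_rtdose: format error, modality is ",
         if (is.null(modality)) "absent" else modality,
         " (expected RTDOSE)", call. = FALSE)
  orient <- el_nums(els, "0020,0037")
  if (is.null(orient) || max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("read_rtdose: unsupported-geometry error, tilted orientation matrix",
         call. = FALSE)
  rows <- el_us(els, "0028,0010"); cols <- el_us(els, "0028,0011")
  nframes <- as.integer(el_nums(els, "0028,0008"))
  if (is.null(rows) || is.null(cols) || length(nframes) != 1L)
    stop("read_rtdose: format error, missing grid dimensions", call. = FALSE)
  ipp <- el_nums(els, "0020,0032")
  psp <- el_nums(els, "0028,0030")
  gfo <- el_nums(els, "3004,000c")
  scaling <- el_nums(els, "3004,000e")
  bits <- el_us(els, "0028,0100")
  if (is.null(gfo) || length(gfo) != nframes)
    stop("read_rtdose: format error, grid-frame offset vector missing or wrong length",
         call. = FALSE)
  dz <- if (nframes > 1) diff(gfo) else 1
  if (nframes > 1 && (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-6))
    stop("read_rtdose: unsupported-geometry error, non-uniform frame offsets",
         call. = FALSE)
  if (is.null(bits) || bits != 32L)
    stop("read_rtdose: format error, only 32-bit pixel data supported", call. = FALSE)
  px <- els[["7fe0,0010"]]
  if (is.null(px))
    stop("read_rtdose: format error, no pixel data", call. = FALSE)
  n <- as.integer(rows) * as.integer(cols) * nframes
  ints <- readBin(px$bytes, "integer", n, size = 4, endian = "little")
  vals <- array(scaling[1] * ints, dim = c(cols, rows, nframes))
  dose_grid(vals,
            origin = ipp + c(0, 0, gfo[1]),
            spacing = c(psp[2], psp[1], dz[1]))
}
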