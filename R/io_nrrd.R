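# Minimal NRRD reader/writer for research dose grids and 0/1 masks.
# Supports 3D fields, diagonal space directions (axis-aligned), little-endian
# raw or whitespace text encodings, types double/float/int/short/uchar.

nrrd_type_info <- list(
  "double"        = list(what = "double",  size = 8L, signed = TRUE),
  "float"         = list(what = "double",  size = 4L, signed = TRUE),
  "int"           = list(what = "integer", size = 4L, signed = TRUE),
  "short"         = list(what = "integer", size = 2L, signed = TRUE),
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  "uchar"         = list(what = "integer", size = 1L, signed = FALSE)
)

#' Write a dose grid or mask as NRRD
#'
#' Plain research-grid format: NRRD0004 header with diagonal space
#' directions. Dose grids are written as `double`, masks as `unsigned char`
#' 0/1. `encoding = "text"` produces an all-ASCII file.
#'
#' @param x a [dose_grid()] or [structure_mask()].
#' @param path output path.
#' @param encoding `"raw"` (little-endian binary) or `"text"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  is_mask <- inherits(x, "structure_mask")
  if (!is_mask && !inherits(x, "dose_grid"))
    stop("write_nrrd: need a dose_grid or structure_mask", call. = FALSE)
  d <- dim(x$values)
  type <- if (is_mask) "unsigned char" else "double"
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("encoding: %s", encoding),
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            x$spacing[1], x$spacing[2], x$spacing[3]),
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            x$origin[1], x$origin[2], x$origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (encoding == "raw") {
    if (is_mask) {
      writeBin(as.raw(as.integer(x$values)), con)
    } else {
      writeBin(as.double(x$values), con, size = 8, endian = "little")
    }
  } else {
    vals <- if (is_mask) as.integer(x$values) else as.double(x$values)
    writeBin(charToRaw(paste(format(vals, digits = 17, trim = TRUE,
                                    scientific = FALSE),
                             collapse = "\n")), con)
  }
  invisible(path)
}

parse_nrrd_vec <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", s), "[, ]+")[[1]])
}

#' Read an NRRD grid
#'
#' @param path path to an NRRD file written by [write_nrrd()] or a compatible
#'   tool (3D, diagonal space directions, raw little-endian or text encoding).
#' @param as_mask return a [structure_mask()] (values coerced to logical)?
#' @return A [dose_grid()] or, with `as_mask = TRUE`, a [structure_mask()].
#' @export
read_nrrd <- function(path, as_mask = FALSE) {
  bytes <- readBin(path, raw(), file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(0x0a))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end))
    stop("read_nrrd: format error, no end-of-header blank line", call. = FALSE)
  hdr <- strsplit(rawToChar(bytes[1:(hdr_end - 2L)]), "\n")[[1]]
  if (!grepl("^NRRD000[1-9]$", hdr[1]))
    stop("read_nrrd: format error, bad magic '", hdr[1], "'", call. = FALSE)
  fields <- list()
  for (line in hdr[-1]) {
    if (grepl("^\\s*#", line) || !nzchar(trimws(line))) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  type <- fields[["type"]]
  ti <- nrrd_type_info[[type]]
  if (is.null(ti))
    stop("read_nrrd: format error, unsupported type '", type, "'", call. = FALSE)
  if (!identical(fields[["dimension"]], "3"))
    stop("read_nrrd: unsupported-geometry error, only 3D grids supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  n <- prod(sizes)
  dirs <- regmatches(fields[["space directions"]],
                     gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
  M <- do.call(rbind, lapply(dirs, parse_nrrd_vec))
  if (nrow(M) != 3 || any(abs(M[upper.tri(M) | lower.tri(M)]) > 1e-9))
    stop("read_nrrd: unsupported-geometry error, space directions not diagonal",
         call. = FALSE)
  spacing <- diag(M)
  origin <- if (!is.null(fields[["space origin"]]))
    parse_nrrd_vec(fields[["space origin"]]) else c(0, 0, 0)
  enc <- fields[["encoding"]]
  data_bytes <- bytes[(hdr_end + 1L):length(bytes)]
  if (enc == "raw") {
    endian <- fields[["endian"]]
    if (!is.null(endian) && endian == "big")
      stop("read_nrrd: format error, big-endian raw data unsupported", call. = FALSE)
    vals <- readBin(data_bytes, ti$what, n, size = ti$size,
                    signed = if (ti$size < 4) ti$signed else TRUE,
                    endian = "little")
  } else if (enc %in% c("text", "txt", "ascii")) {
    vals <- as.numeric(strsplit(trimws(rawToChar(data_bytes)), "\\s+")[[1]])
  } else {
    stop("read_nrrd: format error, unsupported encoding '", enc, "'", call. = FALSE)
  }
  if (length(vals) < n)
    stop("read_nrrd: format error, data shorter than declared sizes", call. = FALSE)
  arr <- array(as.double(vals[1:n]), dim = sizes)
  if (as_mask)
    structure_mask(arr != 0, origin = origin, spacing = spacing)
  else
    dose_grid(arr, origin = origin, spacing = spacing)
}
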