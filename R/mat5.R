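# Minimal MAT-file (level 5) reader/writer: the subset the .nirs / .proc
# containers need. Little-endian, uncompressed elements only; supported array
# classes are double (real), char, struct (1x1), and cell. Numeric data stored
# as miDOUBLE on write; on read any integer/single payload is widened to
# double. Compressed (miCOMPRESSED) and complex arrays are rejected with a
# clear error rather than mis-read.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L
MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L

.pad8 <- function(n) (8L - n %% 8L) %% 8L

.raw_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.element_raw <- function(type, payload) {
  n <- length(payload)
  c(.raw_uint32(type), .raw_uint32(n), payload, raw(.pad8(n)))
}

.double_payload <- function(x) writeBin(as.double(x), raw(), size = 8L, endian = "little")

# Serialize one MATLAB array (with name) as a full miMATRIX element.
.serialize_matrix <- function(value, name) {
  if (is.null(value)) value <- matrix(numeric(0), 0L, 0L)
  if (is.character(value)) {
    stopifnot(length(value) == 1L)
    cls <- MX_CHAR
    dims <- c(if (nchar(value) > 0L) 1L else 0L, nchar(value))
    data <- .element_raw(MI_UINT16,
      writeBin(as.integer(utf8ToInt(value)), raw(), size = 2L, endian = "little"))
  } else if (is.list(value)) {
    nm <- names(value)
    if (!is.null(nm) && all(nzchar(nm))) {
      cls <- MX_STRUCT
      dims <- c(1L, 1L)
      fn_len <- 32L
      name_raw <- raw(0)
      for (f in nm) {
        b <- charToRaw(f)
        if (length(b) >= fn_len) stop("struct field name too long: ", f)
        name_raw <- c(name_raw, b, raw(fn_len - length(b)))
      }
      data <- c(
        .element_raw(MI_INT32, .raw_uint32(fn_len)),
        .element_raw(MI_INT8, name_raw),
        do.call(c, lapply(value, .serialize_matrix, name = "")))
    } else {
      cls <- MX_CELL
      dims <- c(length(value), if (length(value) > 0L) 1L else 0L)
      data <- if (length(value)) do.call(c, lapply(value, .serialize_matrix, name = "")) else raw(0)
    }
  } else if (is.numeric(value) || is.logical(value)) {
    cls <- MX_DOUBLE
    dims <- if (is.matrix(value)) dim(value) else c(1L, length(value))
    data <- .element_raw(MI_DOUBLE, .double_payload(as.double(value)))
  } else {
    stop("unsupported type for MAT serialization: ", class(value)[1L])
  }
  flags <- c(.raw_uint32(cls), .raw_uint32(0L))
  body <- c(
    .element_raw(MI_UINT32, flags),
    .element_raw(MI_INT32, .raw_uint32(dims)),
    .element_raw(MI_INT8, charToRaw(name)),
    data)
  .element_raw(MI_MATRIX, body)
}

#' Write variables to a MAT (level 5) container
#'
#' Writes a named list of R objects as MATLAB variables. Numeric
#' vectors/matrices become double arrays, strings become char arrays, named
#' lists become 1x1 structs, and unnamed lists become cell arrays.
#'
#' @param vars Named list of variables to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @keywords internal
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by nirsconn on %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8L), con)                                 # subsystem offset
  writeBin(c(as.raw(0x00), as.raw(0x01)), con)           # version 0x0100
  writeBin(charToRaw("IM"), con)                         # little-endian marker
  for (nm in names(vars)) {
    writeBin(.serialize_matrix(vars[[nm]], nm), con)
  }
  invisible(path)
}

.read_u32 <- function(buf, pos) {
  v <- as.integer(buf[pos:(pos + 3L)])
  v[1] + v[2] * 256 + v[3] * 65536 + v[4] * 16777216
}

# Parse one tagged data element; returns list(type, data (raw), next_pos).
.parse_element <- function(buf, pos) {
  tf <- .read_u32(buf, pos)
  small_bytes <- tf %/% 65536
  if (small_bytes > 0) {               # small data element format
    type <- tf %% 65536
    data <- if (small_bytes > 0) buf[(pos + 4L):(pos + 3L + small_bytes)] else raw(0)
    list(type = type, data = data, next_pos = pos + 8L)
  } else {
    type <- tf
    nb <- .read_u32(buf, pos + 4L)
    data <- if (nb > 0) buf[(pos + 8L):(pos + 7L + nb)] else raw(0)
    list(type = type, data = data, next_pos = pos + 8L + nb + .pad8(nb))
  }
}

.decode_numeric <- function(type, data) {
  switch(as.character(type),
    "1" = as.double(readBin(data, integer(), n = length(data), size = 1L, signed = TRUE)),
    "2" = as.double(readBin(data, integer(), n = length(data), size = 1L, signed = FALSE)),
    "3" = as.double(readBin(data, integer(), n = length(data) %/% 2L, size = 2L,
                            signed = TRUE, endian = "little")),
    "4" = as.double(readBin(data, integer(), n = length(data) %/% 2L, size = 2L,
                            signed = FALSE, endian = "little")),
    "5" = as.double(readBin(data, integer(), n = length(data) %/% 4L, size = 4L,
                            endian = "little")),
    "6" = {v <- readBin(data, integer(), n = length(data) %/% 4L, size = 4L,
                        endian = "little"); ifelse(v < 0, v + 4294967296, as.double(v))},
    "7" = readBin(data, double(), n = length(data) %/% 4L, size = 4L, endian = "little"),
    "9" = readBin(data, double(), n = length(data) %/% 8L, size = 8L, endian = "little"),
    stop("unsupported MAT numeric data type: ", type))
}

.decode_char <- function(type, data) {
  if (type == MI_UINT16) {
    codes <- readBin(data, integer(), n = length(data) %/% 2L, size = 2L,
                     signed = FALSE, endian = "little")
    intToUtf8(codes)
  } else if (type %in% c(MI_INT8, MI_UINT8, MI_UTF8)) {
    rawToChar(data)
  } else stop("unsupported MAT char data type: ", type)
}

# Parse a miMATRIX payload into an R object; returns list(name, value).
.parse_matrix <- function(body) {
  pos <- 1L
  el <- .parse_element(body, pos); pos <- el$next_pos
  flags_words <- readBin(el$data, integer(), n = 2L, size = 4L, endian = "little")
  cls <- bitwAnd(flags_words[1L], 0xFFL)
  complex_flag <- bitwAnd(flags_words[1L], 0x0800L) != 0L
  if (complex_flag) stop("complex-valued MAT arrays are not supported")
  el <- .parse_element(body, pos); pos <- el$next_pos
  dims <- readBin(el$data, integer(), n = length(el$data) %/% 4L, size = 4L,
                  endian = "little")
  el <- .parse_element(body, pos); pos <- el$next_pos
  name <- rawToChar(el$data)

  if (cls == MX_DOUBLE || (cls >= 7L && cls <= 15L)) {
    el <- .parse_element(body, pos)
    vals <- .decode_numeric(el$type, el$data)
    value <- if (length(dims) == 2L) {
      matrix(vals, nrow = dims[1L], ncol = dims[2L])
    } else array(vals, dim = dims)
  } else if (cls == MX_CHAR) {
    el <- .parse_element(body, pos)
    value <- .decode_char(el$type, el$data)
  } else if (cls == MX_STRUCT) {
    if (prod(dims) != 1L) stop("only 1x1 MAT structs are supported")
    el <- .parse_element(body, pos); pos <- el$next_pos
    fn_len <- readBin(el$data, integer(), n = 1L, size = 4L, endian = "little")
    el <- .parse_element(body, pos); pos <- el$next_pos
    nfields <- length(el$data) %/% fn_len
    fnames <- vapply(seq_len(nfields), function(i) {
      b <- el$data[((i - 1L) * fn_len + 1L):(i * fn_len)]
      rawToChar(b[b != as.raw(0L)])
    }, character(1L))
    value <- vector("list", nfields)
    names(value) <- fnames
    for (i in seq_len(nfields)) {
      sub <- .parse_element(body, pos); pos <- sub$next_pos
      if (sub$type != MI_MATRIX) stop("malformed struct field")
      value[[i]] <- .parse_matrix(sub$data)$value
    }
  } else if (cls == MX_CELL) {
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      sub <- .parse_element(body, pos); pos <- sub$next_pos
      if (sub$type != MI_MATRIX) stop("malformed cell element")
      value[[i]] <- .parse_matrix(sub$data)$value
    }
  } else if (cls == 5L) {
    stop("sparse MAT arrays are not supported")
  } else {
    stop("unsupported MAT array class: ", cls)
  }
  list(name = name, value = value)
}

#' Read a MAT (level 5) container
#'
#' @param path File path.
#' @return Named list of variables. Numeric arrays come back as double
#'   matrices, char arrays as strings, structs as named lists, cells as
#'   unnamed lists.
#' @keywords internal
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, raw(), n = file.info(path)$size)
  if (length(buf) < 128L) stop("not a MAT-file (too short): ", path)
  endian <- rawToChar(buf[127:128])
  if (endian == "MI") stop("big-endian MAT-files are not supported")
  if (endian != "IM") stop("not a MAT level-5 file: ", path)
  pos <- 129L
  out <- list()
  while (pos <= length(buf)) {
    el <- .parse_element(buf, pos)
    pos <- el$next_pos
    if (el$type == MI_COMPRESSED)
      stop("compressed MAT elements are not supported; save uncompressed (e.g. scipy.io.savemat(..., do_compression=False))")
    if (el$type != MI_MATRIX) stop("unexpected top-level MAT element type: ", el$type)
    m <- .parse_matrix(el$data)
    out[[m$name]] <- m$value
  }
  out
}
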