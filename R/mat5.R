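# Minimal MAT-file (Level 5) codec in base R. Supports what Ninapro files
# need: top-level real numeric matrices (double/single/int8..uint64 storage),
# character arrays, and zlib-compressed (miCOMPRESSED) elements. Cell/struct
# arrays are skipped with a warning. Written files use doubles for signal
# data and int32 for label vectors, uncompressed, little-endian.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L; MI_UTF16 <- 17L

MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L
MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L
MX_INT32 <- 12L; MX_UINT32 <- 13L; MX_INT64 <- 14L; MX_UINT64 <- 15L

mat5_type_bytes <- function(type) {
  switch(as.character(type),
         "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
         "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L, "16" = 1L, "17" = 2L,
         emg_format_error(sprintf("unsupported MAT data type %d", type)))
}

mat5_read_numeric <- function(raw, type, n) {
  con <- rawConnection(raw)
  on.exit(close(con))
  switch(as.character(type),
    "1" = readBin(con, "integer", n, size = 1, signed = TRUE, endian = "little"),
    "2" = readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"),
    "3" = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    "4" = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    "5" = readBin(con, "integer", n, size = 4, endian = "little"),
    "6" = { v <- readBin(con, "integer", n, size = 4, endian = "little")
            v <- as.double(v); v[v < 0] <- v[v < 0] + 4294967296; v },
    "7" = readBin(con, "double", n, size = 4, endian = "little"),
    "9" = readBin(con, "double", n, size = 8, endian = "little"),
    "12" = readBin(con, "double", n, size = 8, endian = "little"),  # approx
    "13" = readBin(con, "double", n, size = 8, endian = "little"),  # approx
    emg_format_error(sprintf("unsupported MAT data type %d", type)))
}

# Parse one data element starting at offset `pos` (1-based) in raw vector.
# Returns list(type, data_raw, next_pos).
mat5_next_element <- function(buf, pos) {
  tag <- readBin(buf[pos:(pos + 3L)], "integer", 1, size = 4, endian = "little")
  small_len <- bitwAnd(bitwShiftR(tag, 16L), 0xFFFFL)
  if (small_len > 0L) {  # small data element: type in low 16 bits, <=4 bytes
    type <- bitwAnd(tag, 0xFFFFL)
    nbytes <- small_len
    data <- buf[(pos + 4L):(pos + 3L + nbytes)]
    list(type = type, data = data, next_pos = pos + 8L)
  } else {
    type <- tag
    nbytes <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", 1, size = 4,
                      endian = "little")
    nbytes <- as.double(nbytes); if (nbytes < 0) nbytes <- nbytes + 4294967296
    data <- if (nbytes > 0) buf[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    pad <- if (type == MI_COMPRESSED) 0 else (8 - nbytes %% 8) %% 8
    list(type = type, data = data, next_pos = pos + 8L + as.integer(nbytes + pad))
  }
}

mat5_parse_matrix <- function(data) {
  pos <- 1L
  flags_el <- mat5_next_element(data, pos); pos <- flags_el$next_pos
  flags <- readBin(flags_el$data[1:4], "integer", 1, size = 4, endian = "little")
  mx_class <- bitwAnd(flags, 0xFFL)
  dims_el <- mat5_next_element(data, pos); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4L,
                  size = 4, endian = "little")
  name_el <- mat5_next_element(data, pos); pos <- name_el$next_pos
  name <- rawToChar(name_el$data)

  if (!(mx_class %in% c(MX_CHAR, MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8,
                        MX_INT16, MX_UINT16, MX_INT32, MX_UINT32,
                        MX_INT64, MX_UINT64)))
    return(list(name = name, value = NULL, skipped = TRUE))

  real_el <- mat5_next_element(data, pos)
  n <- prod(dims)
  if (mx_class == MX_CHAR) {
    if (real_el$type %in% c(MI_UINT16, MI_UTF16)) {
      codes <- mat5_read_numeric(real_el$data, MI_UINT16, n)
      value <- intToUtf8(codes)
    } else {
      value <- rawToChar(real_el$data[seq_len(min(n, length(real_el$data)))])
    }
    return(list(name = name, value = value, skipped = FALSE))
  }
  vals <- mat5_read_numeric(real_el$data, real_el$type, n)
  value <- array(as.double(vals), dim = dims)
  if (length(dims) == 2L && any(dims == 1L)) value <- as.vector(value)
  int_class <- mx_class %in% c(MX_INT8, MX_UINT8, MX_INT16, MX_UINT16,
                               MX_INT32, MX_UINT32)
  list(name = name, value = value, integer_like = int_class, skipped = FALSE)
}

# Read a classic MAT v5 file into a named list of arrays/strings.
read_mat5 <- function(path) {
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 128L) emg_format_error("file too short to be a MAT-file")
  magic <- readBin(buf[127:128], "integer", 2, size = 1, signed = FALSE)
  endian <- rawToChar(buf[127:128])
  if (!endian %in% c("IM", "MI"))
    emg_format_error("not a classic MAT v5 file (bad endian indicator)")
  if (endian == "MI")
    emg_format_error("big-endian MAT files are not supported")

  out <- list()
  pos <- 129L
  n_total <- length(buf)
  while (pos + 7L <= n_total) {
    el <- mat5_next_element(buf, pos)
    pos <- el$next_pos
    payloads <- list(el)
    if (el$type == MI_COMPRESSED) {
      inner <- memDecompress(el$data, type = "gzip")
      payloads <- list(mat5_next_element(inner, 1L))
    }
    for (p in payloads) {
      if (p$type != MI_MATRIX) next
      m <- mat5_parse_matrix(p$data)
      if (isTRUE(m$skipped)) {
        warning(sprintf("skipping unsupported MAT variable '%s'", m$name))
      } else if (nzchar(m$name)) {
        out[[m$name]] <- m$value
      }
    }
  }
  out
}

mat5_pad <- function(con, nbytes) {
  pad <- (8 - nbytes %% 8) %% 8
  if (pad > 0) writeBin(raw(pad), con)
}

mat5_write_element <- function(con, type, data_raw) {
  writeBin(as.integer(c(type, length(data_raw))), con, size = 4,
           endian = "little")
  if (length(data_raw)) writeBin(data_raw, con)
  mat5_pad(con, length(data_raw))
}

mat5_numeric_raw <- function(values, mi_type) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  if (mi_type == MI_DOUBLE)
    writeBin(as.double(values), con, size = 8, endian = "little")
  else if (mi_type == MI_INT32)
    writeBin(as.integer(values), con, size = 4, endian = "little")
  else emg_format_error("writer supports miDOUBLE and miINT32 only")
  rawConnectionValue(con)
}

mat5_matrix_raw <- function(name, values, integer = FALSE) {
  dims <- dim(values) %||% c(length(values), 1L)
  mx_class <- if (integer) MX_INT32 else MX_DOUBLE
  mi_type <- if (integer) MI_INT32 else MI_DOUBLE

  body <- rawConnection(raw(0), "wb")
  on.exit(close(body))
  # array flags
  writeBin(as.integer(c(MI_UINT32, 8L)), body, size = 4, endian = "little")
  writeBin(as.integer(c(mx_class, 0L)), body, size = 4, endian = "little")
  # dimensions
  dim_raw <- writeBin(as.integer(dims), raw(), size = 4, endian = "little")
  writeBin(as.integer(c(MI_INT32, length(dim_raw))), body, size = 4, endian = "little")
  writeBin(dim_raw, body); mat5_pad(body, length(dim_raw))
  # name
  name_raw <- charToRaw(name)
  writeBin(as.integer(c(MI_INT8, length(name_raw))), body, size = 4, endian = "little")
  writeBin(name_raw, body); mat5_pad(body, length(name_raw))
  # real part
  data_raw <- mat5_numeric_raw(values, mi_type)
  writeBin(as.integer(c(mi_type, length(data_raw))), body, size = 4, endian = "little")
  writeBin(data_raw, body); mat5_pad(body, length(data_raw))
  rawConnectionValue(body)
}

# Write a named list of numeric arrays as a classic MAT v5 file.
# `integer_vars` names variables stored as int32 (bitwise round-trip).
write_mat5 <- function(vars, path, integer_vars = character(0)) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- sprintf("MATLAB 5.0 MAT-file, written by emgmotion on %s",
                    format(Sys.time(), "%Y-%m-%d"))
  header_raw <- charToRaw(header)
  length(header_raw) <- 116L
  header_raw[is.na(header_raw)] <- as.raw(32L)
  header_raw[header_raw == as.raw(0)] <- as.raw(32L)
  writeBin(header_raw, con)
  writeBin(raw(8), con)                                   # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
  writeBin(charToRaw("IM"), con)                          # endian indicator
  for (nm in names(vars)) {
    body <- mat5_matrix_raw(nm, vars[[nm]], integer = nm %in% integer_vars)
    mat5_write_element(con, MI_MATRIX, body)
  }
  invisible(path)
}
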