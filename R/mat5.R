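# Minimal MATLAB Level-5 MAT-file codec: uncompressed numeric matrices only.
# Covers the dialect used for treadmill PPG recordings (one double matrix per
# variable, little-endian). Compressed (miCOMPRESSED) elements are rejected.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE_CLASS <- 6L

pad8 <- function(n) (8L - (n %% 8L)) %% 8L

#' Read a Level-5 MAT-file of numeric matrices
#'
#' Supports uncompressed little-endian files containing real numeric arrays
#' (the format used to distribute wrist PPG treadmill recordings). Returns a
#' named list of numeric matrices.
#'
#' @param path file path.
#' @return named list of numeric matrices.
#' @export
read_mat <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128L) stop("not a MAT v5 file (truncated header): ", path)
  endian_tag <- rawToChar(raw[127:128])
  if (endian_tag == "MI") stop("big-endian MAT files are not supported")
  if (endian_tag != "IM") stop("not a MAT v5 file (bad endian tag): ", path)
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(raw)) {
    tag <- parse_tag(raw, pos)
    if (tag$type == MI_COMPRESSED) {
      stop("compressed MAT elements are not supported; save with '-v6' ",
           "or uncompressed '-v7' options")
    }
    if (tag$type == MI_MATRIX) {
      el <- parse_matrix(raw, tag$data_pos, tag$nbytes)
      out[[el$name]] <- el$value
    }
    pos <- tag$next_pos
  }
  out
}

parse_tag <- function(raw, pos) {
  b <- raw[pos:(pos + 3L)]
  # small data element: upper two bytes of the type word carry the byte count
  small <- any(b[3:4] != as.raw(0))
  if (small) {
    type <- readBin(b[1:2], "integer", size = 2, endian = "little")
    nbytes <- readBin(b[3:4], "integer", size = 2, endian = "little")
    list(type = type, nbytes = nbytes, data_pos = pos + 4L,
         next_pos = pos + 8L)
  } else {
    type <- readBin(b, "integer", size = 4, endian = "little")
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4,
                      endian = "little")
    list(type = type, nbytes = nbytes, data_pos = pos + 8L,
         next_pos = pos + 8L + nbytes + pad8(nbytes))
  }
}

read_numeric <- function(raw, pos, nbytes, type) {
  bytes <- raw[pos:(pos + nbytes - 1L)]
  switch(as.character(type),
    "1" = readBin(bytes, "integer", n = nbytes, size = 1, signed = TRUE,
                  endian = "little"),
    "2" = readBin(bytes, "integer", n = nbytes, size = 1, signed = FALSE,
                  endian = "little"),
    "3" = readBin(bytes, "integer", n = nbytes %/% 2L, size = 2, signed = TRUE,
                  endian = "little"),
    "4" = readBin(bytes, "integer", n = nbytes %/% 2L, size = 2,
                  signed = FALSE, endian = "little"),
    "5" = readBin(bytes, "integer", n = nbytes %/% 4L, size = 4,
                  endian = "little"),
    "6" = readBin(bytes, "numeric", n = nbytes %/% 4L, size = 4,
                  endian = "little"),  # uint32 via double not exact; unused here
    "7" = readBin(bytes, "numeric", n = nbytes %/% 4L, size = 4,
                  endian = "little"),
    "9" = readBin(bytes, "numeric", n = nbytes %/% 8L, size = 8,
                  endian = "little"),
    stop("unsupported MAT data type: ", type)
  )
}

parse_matrix <- function(raw, pos, nbytes) {
  # array flags
  tg <- parse_tag(raw, pos)
  flags <- readBin(raw[tg$data_pos:(tg$data_pos + 3L)], "integer", size = 4,
                   endian = "little")
  is_complex <- bitwAnd(flags, bitwShiftL(1L, 11L)) != 0L
  # dimensions
  tg2 <- parse_tag(raw, tg$next_pos)
  dims <- readBin(raw[tg2$data_pos:(tg2$data_pos + tg2$nbytes - 1L)],
                  "integer", n = tg2$nbytes %/% 4L, size = 4,
                  endian = "little")
  # name
  tg3 <- parse_tag(raw, tg2$next_pos)
  name <- if (tg3$nbytes > 0L) {
    rawToChar(raw[tg3$data_pos:(tg3$data_pos + tg3$nbytes - 1L)])
  } else ""
  # real part
  tg <- parse_tag(raw, tg3$next_pos)
  vals <- read_numeric(raw, tg$data_pos, tg$nbytes, tg$type)
  if (is_complex) stop("complex MAT variables are not supported")
  if (length(vals) != prod(dims)) {
    stop("MAT variable '", name, "' has inconsistent size")
  }
  value <- array(as.numeric(vals), dim = dims)
  if (length(dims) == 2L) value <- matrix(value, dims[1L], dims[2L])
  list(name = name, value = value)
}

write_tag <- function(con, type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), con, size = 4, endian = "little")
}

write_padded <- function(con, bytes) {
  writeBin(bytes, con)
  np <- pad8(length(bytes))
  if (np > 0L) writeBin(rep(as.raw(0), np), con)
}

#' Write numeric matrices to a Level-5 MAT-file
#'
#' @param vars named list of numeric matrices or vectors (vectors are written
#'   as 1 x n row matrices, matching the convention of per-window ground-truth
#'   vectors).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- sprintf("MATLAB 5.0 MAT-file, written by ppghr %s",
                    format(Sys.time(), "%Y-%m-%d"))
  hb <- charToRaw(header)
  hb <- c(hb, rep(as.raw(32L), 116L - length(hb)))
  writeBin(hb, con)
  writeBin(rep(as.raw(0), 8L), con)               # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)            # version 0x0100
  writeBin(charToRaw("IM"), con)                  # little-endian tag
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (is.null(dim(v))) v <- matrix(as.numeric(v), nrow = 1L)
    storage.mode(v) <- "double"
    name_raw <- charToRaw(nm)
    n_name <- length(name_raw)
    name_field <- 8L + n_name + pad8(n_name)
    data_field <- 8L + 8L * length(v)              # doubles are 8-aligned
    total <- 16L + 16L + name_field + data_field
    write_tag(con, MI_MATRIX, total)
    write_tag(con, MI_UINT32, 8L)
    writeBin(as.integer(c(MX_DOUBLE_CLASS, 0L)), con, size = 4,
             endian = "little")
    write_tag(con, MI_INT32, 8L)
    writeBin(as.integer(dim(v)), con, size = 4, endian = "little")
    write_tag(con, MI_INT8, n_name)
    write_padded(con, name_raw)
    write_tag(con, MI_DOUBLE, 8L * length(v))
    writeBin(as.numeric(v), con, size = 8, endian = "little")
  }
  invisible(path)
}
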