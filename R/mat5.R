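# Minimal MAT-file (level 5) reader/writer.
#
# Covers the subset of the format the session and spike-sort containers use:
# double-precision numeric arrays, character arrays, cell arrays and scalar
# structs.  Files are written uncompressed and little-endian; the reader also
# accepts zlib-compressed elements (as written by MATLAB >= 7 and scipy) and
# the "small data element" packing.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L; MI_UTF16 <- 17L

MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L
MX_SINGLE <- 7L; MX_INT8 <- 8L; MX_UINT8 <- 9L; MX_INT16 <- 10L
MX_UINT16 <- 11L; MX_INT32 <- 12L; MX_UINT32 <- 13L

pad8 <- function(n) (8L - n %% 8L) %% 8L

# ---- writer ---------------------------------------------------------------

mat5_classify <- function(x) {
  if (is.numeric(x) || is.logical(x)) "numeric"
  else if (is.character(x) && length(x) == 1L) "char"
  else if (is.character(x)) "cell"          # string vector -> cell of strings
  else if (is.data.frame(x)) "cell"         # two-column tables -> n x k cell
  else if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) "struct"
  else if (is.list(x)) "cell"
  else stop("cannot encode object of class '", paste(class(x), collapse = "/"),
            "' in a MAT-5 file", call. = FALSE)
}

mat5_cells <- function(x) {
  # normalize a cell-bound object to a plain list plus dims (column-major)
  if (is.data.frame(x)) {
    cells <- vector("list", nrow(x) * ncol(x))
    for (j in seq_len(ncol(x)))
      for (i in seq_len(nrow(x)))
        cells[[(j - 1L) * nrow(x) + i]] <- x[[j]][[i]]
    list(cells = cells, dims = c(nrow(x), ncol(x)))
  } else if (is.character(x)) {
    list(cells = as.list(x), dims = c(1L, length(x)))
  } else if (!is.null(dim(x))) {
    list(cells = as.list(x), dims = dim(x))
  } else {
    list(cells = x, dims = c(1L, length(x)))
  }
}

mat5_dims <- function(x) {
  switch(mat5_classify(x),
    numeric = if (is.matrix(x)) dim(x) else c(1L, length(x)),
    char    = c(1L, nchar(x, type = "chars")),
    cell    = mat5_cells(x)$dims,
    struct  = c(1L, 1L))
}

# total on-disk size (tag included) of the miMATRIX element for x
mat5_element_size <- function(x, name = "") {
  nd <- length(mat5_dims(x))
  body <- 16L +                               # array flags
    8L + 4L * nd + pad8(4L * nd) +            # dimensions
    8L + nchar(name, type = "bytes") + pad8(nchar(name, type = "bytes"))
  body <- body + switch(mat5_classify(x),
    numeric = 8L + 8L * length(x) + pad8(0L),
    char    = {
      nb <- 2L * nchar(x, type = "chars")
      8L + nb + pad8(nb)
    },
    cell    = sum(vapply(mat5_cells(x)$cells, mat5_element_size, 0L)),
    struct  = {
      flen <- max(c(2L, nchar(names(x), type = "bytes") + 1L))
      nf <- length(x)
      16L + 8L + nf * flen + pad8(nf * flen) +
        sum(vapply(x, mat5_element_size, 0L))
    })
  8L + body
}

mat5_write_tag <- function(con, type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), con, size = 4L, endian = "little")
}

mat5_write_padding <- function(con, n) {
  if (n > 0L) writeBin(raw(n), con)
}

mat5_write_element <- function(con, x, name = "") {
  kind <- mat5_classify(x)
  mat5_write_tag(con, MI_MATRIX, mat5_element_size(x, name) - 8L)
  cls <- switch(kind, numeric = MX_DOUBLE, char = MX_CHAR,
                cell = MX_CELL, struct = MX_STRUCT)
  mat5_write_tag(con, MI_UINT32, 8L)
  writeBin(as.integer(c(cls, 0L)), con, size = 4L, endian = "little")
  dims <- as.integer(mat5_dims(x))
  mat5_write_tag(con, MI_INT32, 4L * length(dims))
  writeBin(dims, con, size = 4L, endian = "little")
  mat5_write_padding(con, pad8(4L * length(dims)))
  nb <- nchar(name, type = "bytes")
  mat5_write_tag(con, MI_INT8, nb)
  if (nb > 0L) writeBin(charToRaw(name), con)
  mat5_write_padding(con, pad8(nb))
  if (kind == "numeric") {
    mat5_write_tag(con, MI_DOUBLE, 8L * length(x))
    writeBin(as.double(x), con, size = 8L, endian = "little")
  } else if (kind == "char") {
    codes <- utf8ToInt(x)
    mat5_write_tag(con, MI_UINT16, 2L * length(codes))
    writeBin(as.integer(codes), con, size = 2L, endian = "little")
    mat5_write_padding(con, pad8(2L * length(codes)))
  } else if (kind == "cell") {
    for (cell in mat5_cells(x)$cells) mat5_write_element(con, cell)
  } else {
    flen <- max(c(2L, nchar(names(x), type = "bytes") + 1L))
    mat5_write_tag(con, MI_INT32, 4L)
    writeBin(as.integer(flen), con, size = 4L, endian = "little")
    mat5_write_padding(con, 4L)
    nf <- length(x)
    mat5_write_tag(con, MI_INT8, nf * flen)
    for (fn in names(x)) {
      fr <- charToRaw(fn)
      writeBin(c(fr, raw(flen - length(fr))), con)
    }
    mat5_write_padding(con, pad8(nf * flen))
    for (field in x) mat5_write_element(con, field)
  }
  invisible(NULL)
}

#' Write variables to a MAT-file (level 5)
#'
#' Writes a named list of R objects as top-level MATLAB variables.  Numeric
#' vectors/matrices become double arrays, single strings become char arrays,
#' unnamed lists, string vectors and data frames become cell arrays, and named
#' lists become scalar structs.  Output is uncompressed little-endian MAT v5,
#' readable by MATLAB, Octave and scipy.io.
#'
#' @param vars named list of variables to store.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_mat()]
#' @export
write_mat <- function(vars, path) {
  if (is.null(names(vars)) || any(!nzchar(names(vars))))
    stop("'vars' must be a fully named list", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by iemgkit on %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  hdr <- charToRaw(desc)
  length(hdr) <- 116L
  hdr[is.na(hdr)] <- as.raw(0x20)
  writeBin(hdr, con)
  writeBin(raw(8L), con)                      # subsystem offset
  writeBin(as.integer(0x0100), con, size = 2L, endian = "little")
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) mat5_write_element(con, vars[[nm]], nm)
  invisible(path)
}

# ---- reader ---------------------------------------------------------------

mat5_cursor <- function(raw) {
  env <- new.env(parent = emptyenv())
  env$raw <- raw
  env$pos <- 1L
  env
}

cur_take <- function(cur, n) {
  if (cur$pos + n - 1L > length(cur$raw))
    stop("unexpected end of MAT-file", call. = FALSE)
  out <- cur$raw[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + n
  out
}

cur_uint32 <- function(cur) {
  v <- readBin(cur_take(cur, 4L), "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# reads a data-element tag; returns list(type, nbytes, small_payload or NULL)
mat5_read_tag <- function(cur) {
  first <- cur_take(cur, 4L)
  hi <- readBin(first[3:4], "integer", size = 2L, signed = FALSE,
                endian = "little")
  if (hi != 0L) {       # small data element: size in upper 16 bits
    type <- readBin(first[1:2], "integer", size = 2L, signed = FALSE,
                    endian = "little")
    list(type = type, nbytes = hi, payload = cur_take(cur, 4L)[seq_len(hi)])
  } else {
    type <- readBin(first, "integer", size = 4L, endian = "little")
    list(type = type, nbytes = cur_uint32(cur), payload = NULL)
  }
}

mat5_decode_numeric <- function(bytes, type) {
  switch(as.character(type),
    "1" = readBin(bytes, "integer", n = length(bytes), size = 1L),
    "2" = readBin(bytes, "integer", n = length(bytes), size = 1L,
                  signed = FALSE),
    "3" = readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                  endian = "little"),
    "4" = readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                  signed = FALSE, endian = "little"),
    "5" = readBin(bytes, "integer", n = length(bytes) %/% 4L, size = 4L,
                  endian = "little"),
    "6" = {
      v <- readBin(bytes, "integer", n = length(bytes) %/% 4L, size = 4L,
                   endian = "little")
      ifelse(v < 0, v + 2^32, v)
    },
    "7" = readBin(bytes, "numeric", n = length(bytes) %/% 4L, size = 4L,
                  endian = "little"),
    "9" = readBin(bytes, "numeric", n = length(bytes) %/% 8L, size = 8L,
                  endian = "little"),
    "16" = utf8ToInt(rawToChar(bytes)),
    "17" = readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little"),
    stop("unsupported MAT data type code ", type, call. = FALSE))
}

# reads one subelement and returns its decoded numeric payload
mat5_read_sub <- function(cur) {
  tag <- mat5_read_tag(cur)
  if (!is.null(tag$payload)) return(mat5_decode_numeric(tag$payload, tag$type))
  bytes <- cur_take(cur, tag$nbytes)
  cur$pos <- cur$pos + pad8(tag$nbytes)
  mat5_decode_numeric(bytes, tag$type)
}

mat5_shape <- function(values, dims) {
  if (length(dims) == 2L && all(dims > 1L)) {
    matrix(values, nrow = dims[1], ncol = dims[2])
  } else if (length(dims) > 2L) {
    array(values, dim = dims)
  } else {
    values
  }
}

# parses one miMATRIX element body; returns list(name, value)
mat5_read_matrix <- function(cur) {
  flags_tag <- mat5_read_tag(cur)
  flags_raw <- if (is.null(flags_tag$payload)) cur_take(cur, 8L) else
    flags_tag$payload
  cls <- as.integer(flags_raw[1])
  dims <- as.integer(mat5_read_sub(cur))
  name_tag <- mat5_read_tag(cur)
  name <- if (!is.null(name_tag$payload)) {
    rawToChar(name_tag$payload)
  } else if (name_tag$nbytes > 0L) {
    nm <- rawToChar(cur_take(cur, name_tag$nbytes))
    cur$pos <- cur$pos + pad8(name_tag$nbytes)
    nm
  } else ""
  value <-
    if (cls == MX_CELL) {
      n <- prod(dims)
      cells <- vector("list", n)
      for (i in seq_len(n)) {
        tag <- mat5_read_tag(cur)
        if (tag$type != MI_MATRIX)
          stop("malformed cell array in MAT-file", call. = FALSE)
        end <- cur$pos + tag$nbytes
        cells[[i]] <- if (tag$nbytes == 0L) numeric(0) else
          mat5_read_matrix(cur)$value
        cur$pos <- end + pad8(tag$nbytes)
      }
      if (length(dims) == 2L && all(dims > 1L)) dim(cells) <- dims
      cells
    } else if (cls == MX_STRUCT) {
      flen <- as.integer(mat5_read_sub(cur))
      fn_tag <- mat5_read_tag(cur)
      fn_bytes <- if (!is.null(fn_tag$payload)) fn_tag$payload else {
        b <- cur_take(cur, fn_tag$nbytes)
        cur$pos <- cur$pos + pad8(fn_tag$nbytes)
        b
      }
      nf <- length(fn_bytes) %/% flen
      fields <- vapply(seq_len(nf), function(i) {
        chunk <- fn_bytes[((i - 1L) * flen + 1L):(i * flen)]
        rawToChar(chunk[chunk != as.raw(0L)])
      }, "")
      out <- vector("list", nf)
      names(out) <- fields
      for (i in seq_len(nf)) {
        tag <- mat5_read_tag(cur)
        end <- cur$pos + tag$nbytes
        out[[i]] <- if (tag$nbytes == 0L) numeric(0) else
          mat5_read_matrix(cur)$value
        cur$pos <- end + pad8(tag$nbytes)
      }
      out
    } else if (cls == MX_CHAR) {
      codes <- mat5_read_sub(cur)
      if (length(dims) == 2L && dims[1] > 1L) {
        m <- matrix(codes, nrow = dims[1], ncol = dims[2])
        apply(m, 1L, function(row) intToUtf8(row[row != 0L]))
      } else {
        intToUtf8(codes)
      }
    } else if (cls %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                          MX_UINT16, MX_INT32, MX_UINT32)) {
      mat5_shape(as.double(mat5_read_sub(cur)), dims)
    } else {
      stop("unsupported MAT array class ", cls, call. = FALSE)
    }
  list(name = name, value = value)
}

#' Read a MAT-file (level 5)
#'
#' Parses the top-level variables of a little-endian MAT v5 file into a named
#' list.  Numeric arrays are returned as doubles (matrices keep their shape,
#' row/column vectors are flattened), char arrays as strings, cell arrays as
#' lists and structs as named lists.  Both plain and zlib-compressed elements
#' are understood.
#'
#' @param path file path.
#' @return named list of variables.
#' @seealso [write_mat()]
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 128L)
    stop("not a MAT-5 file (truncated header): ", path, call. = FALSE)
  endian <- rawToChar(bytes[127:128])
  if (endian == "MI")
    stop("big-endian MAT-files are not supported", call. = FALSE)
  if (endian != "IM")
    stop("not a MAT-5 file (bad endian indicator): ", path, call. = FALSE)
  cur <- mat5_cursor(bytes)
  cur$pos <- 129L
  out <- list()
  while (cur$pos + 8L <= length(bytes)) {
    tag <- mat5_read_tag(cur)
    if (tag$type == MI_COMPRESSED) {
      # compressed elements are not required to be 8-aligned: no padding skip
      payload <- cur_take(cur, tag$nbytes)
      inner <- mat5_cursor(memDecompress(payload, type = "gzip"))
      itag <- mat5_read_tag(inner)
      if (itag$type == MI_MATRIX) {
        el <- mat5_read_matrix(inner)
        out[[el$name]] <- el$value
      }
    } else if (tag$type == MI_MATRIX) {
      end <- cur$pos + tag$nbytes
      el <- mat5_read_matrix(cur)
      out[[el$name]] <- el$value
      cur$pos <- end + pad8(tag$nbytes)
    } else {
      cur$pos <- cur$pos + tag$nbytes + pad8(tag$nbytes)
    }
  }
  out
}
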