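# Minimal MATLAB v5 (.mat) reader.
#
# Supports what Imspector exports need: numeric arrays (double/single/ints),
# logical arrays, char arrays, struct and cell arrays, and zlib-compressed
# data elements. No sparse matrices, no v7.3/HDF5.

MI_TYPES <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
              miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
              miINT64 = 12, miUINT64 = 13, miMATRIX = 14,
              miCOMPRESSED = 15, miUTF8 = 16)

#' Read a MATLAB v5 MAT-file
#'
#' Minimal reader for the MAT v5 container (the format Imspector uses for
#' localization exports). Numeric arrays become R arrays/matrices, structs
#' become named lists, cell arrays become lists.
#'
#' @param path file path.
#' @return named list of top-level variables.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128) stop_mfx("not a MAT v5 file (too short): %s", path)
  endian_tag <- rawToChar(raw[127:128])
  swap <- identical(endian_tag, "IM")
  endian <- if (swap) "little" else "big"
  # Header magic sanity: version field should be 0x0100 in file byte order.
  pos <- 129L
  vars <- list()
  while (pos <= length(raw)) {
    el <- mat5_element(raw, pos, endian)
    pos <- el$next_pos
    if (is.null(el$payload)) next
    if (el$type == MI_TYPES[["miCOMPRESSED"]]) {
      inflated <- mat5_inflate(el$payload)
      sub <- mat5_element(inflated, 1L, endian)
      v <- mat5_parse_matrix(sub$payload, endian)
    } else if (el$type == MI_TYPES[["miMATRIX"]]) {
      v <- mat5_parse_matrix(el$payload, endian)
    } else next
    if (!is.null(v)) vars[[v$name]] <- v$value
  }
  vars
}

mat5_inflate <- function(payload) {
  for (type in c("gzip", "unknown")) {
    out <- tryCatch(memDecompress(payload, type = type),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(out) && length(out)) return(out)
  }
  stop_mfx("cannot inflate compressed MAT element")
}

# Read one tagged data element starting at pos; returns type, payload raw
# vector and position of the next element (8-byte aligned).
mat5_element <- function(raw, pos, endian) {
  word <- readBin(raw[pos:(pos + 3)], "integer", 1, 4, endian = endian)
  small_len <- bitwAnd(bitwShiftR(word, 16), 0xFFFF)
  if (small_len > 0) {  # small data element: length packed into the tag
    type <- bitwAnd(word, 0xFFFF)
    payload <- raw[(pos + 4):(pos + 3 + small_len)]
    return(list(type = type, payload = payload, next_pos = pos + 8L))
  }
  type <- word
  nbytes <- readBin(raw[(pos + 4):(pos + 7)], "integer", 1, 4, endian = endian)
  payload <- if (nbytes > 0) raw[(pos + 8):(pos + 7 + nbytes)] else raw[0]
  adv <- 8L + nbytes
  if (type != MI_TYPES[["miCOMPRESSED"]]) adv <- adv + (-nbytes %% 8L)
  list(type = type, payload = payload, next_pos = pos + as.integer(adv))
}

mat5_numeric <- function(type, payload, endian) {
  spec <- switch(as.character(type),
    `1` = list(what = "integer", size = 1, signed = TRUE),
    `2` = list(what = "integer", size = 1, signed = FALSE),
    `3` = list(what = "integer", size = 2, signed = TRUE),
    `4` = list(what = "integer", size = 2, signed = FALSE),
    `5` = list(what = "integer", size = 4, signed = TRUE),
    `6` = list(what = "integer", size = 4, signed = TRUE),  # uint32 as int
    `7` = list(what = "double", size = 4, signed = TRUE),
    `9` = list(what = "double", size = 8, signed = TRUE),
    `12` = list(what = "double", size = 8, signed = TRUE),  # int64 lossy > 2^53
    `13` = list(what = "double", size = 8, signed = TRUE),
    `16` = list(what = "character", size = 1, signed = FALSE),
    NULL)
  if (is.null(spec)) stop_mfx("unsupported MAT data type %d", type)
  n <- length(payload) %/% spec$size
  if (spec$what == "character") return(rawToChar(payload))
  readBin(payload, spec$what, n, spec$size, signed = spec$signed,
          endian = endian)
}

mat5_parse_matrix <- function(payload, endian) {
  pos <- 1L
  flags_el <- mat5_element(payload, pos, endian); pos <- flags_el$next_pos
  flags <- readBin(flags_el$payload[1:4], "integer", 1, 4, endian = endian)
  mx_class <- bitwAnd(flags, 0xFF)
  dims_el <- mat5_element(payload, pos, endian); pos <- dims_el$next_pos
  dims <- mat5_numeric(dims_el$type, dims_el$payload, endian)
  name_el <- mat5_element(payload, pos, endian); pos <- name_el$next_pos
  name <- if (length(name_el$payload))
    rawToChar(name_el$payload[name_el$payload != as.raw(0)]) else ""

  value <- NULL
  if (mx_class %in% 6:13 || mx_class == 9) {      # numeric / logical classes
    data_el <- mat5_element(payload, pos, endian)
    v <- mat5_numeric(data_el$type, data_el$payload, endian)
    value <- if (length(dims) > 2) array(v, dim = dims)
             else if (length(dims) == 2 && any(dims != 1))
               matrix(v, dims[1], dims[2]) else v
  } else if (mx_class == 4) {                      # char
    data_el <- mat5_element(payload, pos, endian)
    v <- mat5_numeric(data_el$type, data_el$payload, endian)
    value <- if (is.character(v)) v else
      paste(intToUtf8(v, multiple = TRUE), collapse = "")
  } else if (mx_class == 2) {                      # struct
    fl_el <- mat5_element(payload, pos, endian); pos <- fl_el$next_pos
    flen <- mat5_numeric(fl_el$type, fl_el$payload, endian)[1]
    fn_el <- mat5_element(payload, pos, endian); pos <- fn_el$next_pos
    nfields <- length(fn_el$payload) %/% flen
    fnames <- vapply(seq_len(nfields), function(i) {
      b <- fn_el$payload[((i - 1) * flen + 1):(i * flen)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    nelem <- prod(dims)
    fields <- vector("list", nfields * nelem)
    for (i in seq_len(nfields * nelem)) {
      el <- mat5_element(payload, pos, endian); pos <- el$next_pos
      fields[[i]] <- mat5_parse_matrix(el$payload, endian)$value
    }
    if (nelem == 1) {
      value <- setNames(fields, fnames)
    } else {  # array of structs -> list of named lists, element-major
      value <- lapply(seq_len(nelem), function(e)
        setNames(fields[(e - 1) * nfields + seq_len(nfields)], fnames))
    }
  } else if (mx_class == 1) {                      # cell
    nelem <- prod(dims)
    value <- vector("list", nelem)
    for (i in seq_len(nelem)) {
      el <- mat5_element(payload, pos, endian); pos <- el$next_pos
      value[[i]] <- mat5_parse_matrix(el$payload, endian)$value
    }
  } else {
    stop_mfx("unsupported MAT array class %d", mx_class)
  }
  list(name = name, value = value)
}
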