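#' Read an ABIF (.fsa) fragment-analysis container
#'
#' Minimal reader for the Applied Biosystems ABIF container used by capillary
#' instruments: parses the tag directory and decodes numeric and string
#' entries. Returns every tag keyed as `"NAME.number"` (e.g. `DATA.1` for the
#' first fluorescence channel, `DATA.105` for the size-standard channel on
#' 3730-class instruments).
#'
#' @param path Path to an ABIF file.
#' @return A named list of decoded tag values; unsupported element types are
#'   returned as raw vectors.
#' @seealso [fsa_trace()] to extract a channel as a trace tibble.
#' @export
read_abif <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "ABIF")) {
    abort(sprintf("`%s` is not an ABIF container (magic `%s`).", path, magic),
      class = "repquant_format_error")
  }
  readBin(con, "integer", 1L, size = 2L, endian = "big") # version
  dir_entry <- read_abif_entry(con)
  seek(con, dir_entry$dataoffset)
  entries <- purrr::map(seq_len(dir_entry$numelements),
    ~ read_abif_entry(con))
  out <- purrr::map(entries, function(e) {
    if (e$datasize <= 4L) {
      data <- e$raw_offset[seq_len(e$datasize)]
    } else {
      seek(con, e$dataoffset)
      data <- readBin(con, "raw", e$datasize)
    }
    decode_abif(data, e$elementtype, e$numelements)
  })
  names(out) <- purrr::map_chr(entries,
    ~ sprintf("%s.%d", .x$name, .x$number))
  out
}

read_abif_entry <- function(con) {
  name <- readChar(con, 4L, useBytes = TRUE)
  number <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  elementtype <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  elementsize <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  numelements <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  datasize <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  raw_offset <- readBin(con, "raw", 4L)
  readBin(con, "raw", 4L) # datahandle, unused
  dataoffset <- sum(as.integer(raw_offset) * c(256^3, 256^2, 256, 1))
  list(name = name, number = number, elementtype = elementtype,
    elementsize = elementsize, numelements = numelements,
    datasize = datasize, dataoffset = dataoffset, raw_offset = raw_offset)
}

decode_abif <- function(data, type, n) {
  switch(as.character(type),
    "1" = as.integer(readBin(data, "integer", n, size = 1L, signed = FALSE)),
    "2" = rawToChar(data),
    "3" = readBin(data, "integer", n, size = 2L, signed = FALSE,
      endian = "big"),
    "4" = readBin(data, "integer", n, size = 2L, endian = "big"),
    "5" = readBin(data, "integer", n, size = 4L, endian = "big"),
    "7" = readBin(data, "numeric", n, size = 4L, endian = "big"),
    "8" = readBin(data, "numeric", n, size = 8L, endian = "big"),
    "18" = rawToChar(data[-1L]), # pString: leading length byte
    "19" = rawToChar(data[data != as.raw(0L)]), # cString: NUL-terminated
    data
  )
}

#' Extract a fluorescence channel from an ABIF file as a trace
#'
#' @param path Path to an ABIF (.fsa) file.
#' @param data_tag Tag holding the fluorescence channel, default `"DATA.1"`.
#' @return A tibble with columns `position` (scan index, 1-based) and
#'   `fluorescence`, suitable for [call_peaks()].
#' @export
fsa_trace <- function(path, data_tag = "DATA.1") {
  tags <- read_abif(path)
  if (!data_tag %in% names(tags)) {
    abort(sprintf("Tag `%s` not found in `%s` (available: %s).", data_tag,
      path, paste(head(names(tags), 20L), collapse = ", ")),
      class = "repquant_format_error")
  }
  f <- as.double(tags[[data_tag]])
  tibble::tibble(position = seq_along(f), fluorescence = f)
}
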