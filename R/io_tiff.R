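# Minimal baseline TIFF codec for single-plane grayscale images.
#
# No TIFF-capable R package ships with this toolchain, so the package
# carries its own reader/writer for the only flavours the pipeline
# needs: uncompressed, single-sample grayscale, 8/16-bit unsigned or
# 32-bit float, either byte order on read, little-endian single-strip on
# write.  Output is verified against an independent reader in the test
# suite.

TIFF_TYPE_SIZE <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                    `6` = 1, `7` = 1, `8` = 2, `9` = 4, `10` = 8,
                    `11` = 4, `12` = 8)

#' Write a matrix as a grayscale TIFF
#'
#' Writes an uncompressed single-strip little-endian baseline TIFF.
#' \code{"uint16"} (the camera format) and \code{"uint8"} round and
#' clip; \code{"float32"} stores IEEE single precision, used for phase
#' and index maps.
#'
#' @param m Numeric matrix; row 1 is the top image row.
#' @param path Output file path.
#' @param type \code{"uint16"}, \code{"float32"} or \code{"uint8"}.
#' @return \code{path}, invisibly.
#' @export
write_tiff <- function(m, path, type = c("uint16", "float32", "uint8")) {
  type <- match.arg(type)
  stopifnot(is.matrix(m), is.numeric(m))
  nr <- nrow(m); nc <- ncol(m)
  bits <- switch(type, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- switch(type, uint8 = 1L, uint16 = 1L, float32 = 3L)
  bytes <- nr * nc * (bits %/% 8)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(8 + bytes), con, size = 4, endian = "little")  # IFD offset
  v <- as.vector(t(m))  # TIFF is row-major, top row first
  if (type == "float32") {
    writeBin(as.double(v), con, size = 4, endian = "little")
  } else {
    maxv <- 2^bits - 1
    v <- pmin(pmax(round(v), 0), maxv)
    if (type == "uint16") {
      v <- as.integer(v)
      v[v > 32767L] <- v[v > 32767L] - 65536L  # two's-complement bit pattern
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.raw(v), con)
    }
  }
  entry <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  writeBin(10L, con, size = 2, endian = "little")  # entry count
  entry(256, 4, 1, nc)            # ImageWidth
  entry(257, 4, 1, nr)            # ImageLength
  entry(258, 3, 1, bits)          # BitsPerSample
  entry(259, 3, 1, 1)             # Compression: none
  entry(262, 3, 1, 1)             # Photometric: BlackIsZero
  entry(273, 4, 1, 8)             # StripOffsets
  entry(277, 3, 1, 1)             # SamplesPerPixel
  entry(278, 4, 1, nr)            # RowsPerStrip
  entry(279, 4, 1, bytes)         # StripByteCounts
  entry(339, 3, 1, fmt)           # SampleFormat
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' Read a grayscale TIFF
#'
#' Reads uncompressed single-sample grayscale baseline TIFFs (8/16-bit
#' unsigned or 32-bit float, either byte order, one or more strips).
#' Multi-channel images raise a typed error
#' (\code{holoRI_channels_error}); compressed or tiled files are
#' rejected as unsupported.
#'
#' @param path File path.
#' @return Numeric matrix with attributes \code{bits} and
#'   \code{sample_format} (1 = unsigned integer, 3 = float).
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  rd_int <- function(off, size, n = 1) {
    # signed = FALSE is only legal for sizes 1-2; 4-byte tag values in
    # scope here (offsets, dimensions) stay far below 2^31
    readBin(raw_all[(off + 1):(off + size * n)], "integer",
            n = n, size = size, endian = endian, signed = size >= 4)
  }
  if (rd_int(2, 2) != 42) stop("not a TIFF file: ", path)
  ifd <- rd_int(4, 4)
  n_entries <- rd_int(ifd, 2)
  tags <- list()
  for (e in seq_len(n_entries)) {
    off <- ifd + 2 + (e - 1) * 12
    tag <- rd_int(off, 2)
    typ <- rd_int(off + 2, 2)
    count <- rd_int(off + 4, 4)
    tsz <- TIFF_TYPE_SIZE[[as.character(typ)]]
    val_off <- if (count * tsz <= 4) off + 8 else rd_int(off + 8, 4)
    vals <- if (typ %in% c(3, 8)) rd_int(val_off, 2, count)
      else if (typ %in% c(4, 9)) rd_int(val_off, 4, count)
      else if (typ %in% c(1, 2, 6, 7)) as.integer(raw_all[(val_off + 1):(val_off + count)])
      else rd_int(val_off, 4, count)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      default
    } else v
  }
  nc <- need(256); nr <- need(257)
  bits <- need(258, 1L)
  spp <- need(277, 1L)
  photometric <- need(262, 1L)
  if (length(bits) > 1 || spp > 1 || photometric == 2)
    stop_holo(sprintf("multi-channel image (%d samples/pixel, photometric %d): only single-plane grayscale TIFF is supported",
                      max(spp, length(bits)), photometric),
              "holoRI_channels_error")
  if (need(259, 1L) != 1) stop("compressed TIFF not supported")
  fmt <- need(339, 1L)
  offsets <- need(273)
  counts <- need(279, nr * nc * (bits %/% 8))
  data <- unlist(lapply(seq_along(offsets), function(i) {
    seg <- raw_all[(offsets[i] + 1):(offsets[i] + counts[i])]
    if (fmt == 3) {
      if (bits != 32) stop("only 32-bit float TIFF supported")
      readBin(seg, "double", n = counts[i] / 4, size = 4, endian = endian)
    } else if (bits == 16) {
      readBin(seg, "integer", n = counts[i] / 2, size = 2,
              endian = endian, signed = FALSE)
    } else if (bits == 8) {
      as.integer(seg)
    } else stop("unsupported bit depth: ", bits)
  }))
  if (length(data) != nr * nc) stop("TIFF pixel data does not match dimensions")
  m <- matrix(as.numeric(data), nr, nc, byrow = TRUE)
  attr(m, "bits") <- as.integer(bits)
  attr(m, "sample_format") <- as.integer(fmt)
  m
}

#' Read an interferogram image file
#'
#' Loads a camera frame losslessly.  16-bit files load as-is; 8-bit
#' files are rescaled to the 16-bit range (x257) with a warning;
#' floating-point files are refused unless \code{allow_float = TRUE}.
#'
#' @param path TIFF file path.
#' @param config Optional \code{\link{optical_config}} to attach; by
#'   default a config with matching image shape and package defaults.
#' @param allow_float Accept 32-bit float input.
#' @return An \code{\link{interferogram}}.
#' @export
read_interferogram <- function(path, config = NULL, allow_float = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- read_tiff(path)
  if (attr(m, "sample_format") == 3 && !allow_float)
    stop_holo("floating-point image: pass allow_float = TRUE to accept",
              "holoRI_float_error")
  if (attr(m, "bits") == 8 && attr(m, "sample_format") == 1) {
    warning("8-bit input rescaled to the 16-bit range")
    m <- m * 257
  }
  attr(m, "bits") <- NULL
  attr(m, "sample_format") <- NULL
  if (is.null(config))
    config <- optical_config(image_shape = dim(m))
  if (!all(dim(m) == config$image_shape))
    stop("image shape does not match the configuration")
  interferogram(m, config)
}

#' Write an interferogram to a 16-bit TIFF
#'
#' @param holo An \code{\link{interferogram}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_interferogram <- function(holo, path) {
  stopifnot(inherits(holo, "interferogram"))
  write_tiff(holo$pixels, path, "uint16")
}
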