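# Minimal baseline-TIFF codec: uncompressed, little-endian, single-sample
# 32-bit IEEE float, one strip per page. No R TIFF bindings are assumed;
# the subset written here is readable by Fiji / tifffile / scikit-image.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

tiff_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(u16(value), as.raw(c(0, 0))) else u32(value)
  c(u16(tag), u16(type), u32(count), val)
}

#' Write / read a list of numeric matrices as a multi-page float TIFF
#'
#' Baseline uncompressed little-endian TIFF with one page per matrix and
#' 32-bit IEEE-float samples (values round-trip at single precision).
#'
#' @param slices list of numeric matrices (rows = image rows).
#' @param path file path.
#' @return `write_tiff` returns `path` invisibly; `read_tiff` returns a list
#'   of numeric matrices.
#' @export
write_tiff <- function(slices, path) {
  stopifnot(is.list(slices), length(slices) >= 1L,
            all(vapply(slices, is.matrix, TRUE)))
  n <- length(slices)
  heights <- vapply(slices, nrow, 1L)
  widths <- vapply(slices, ncol, 1L)
  sizes <- 4L * heights * widths
  data_off <- 8L + c(0L, cumsum(sizes))[seq_len(n)]
  ifd_bytes <- 2L + 10L * 12L + 4L  # 10 entries per IFD
  ifd_off <- 8L + sum(sizes) + (seq_len(n) - 1L) * ifd_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)            # "II"
  writeBin(u16(42L), con)
  writeBin(u32(ifd_off[1L]), con)
  for (i in seq_len(n)) {
    # row-major pixel order
    writeBin(as.vector(t(slices[[i]])), con, size = 4L, endian = "little")
  }
  for (i in seq_len(n)) {
    ifd <- c(
      u16(10L),
      tiff_entry(256L, 4L, 1L, widths[i]),     # ImageWidth
      tiff_entry(257L, 4L, 1L, heights[i]),    # ImageLength
      tiff_entry(258L, 3L, 1L, 32L),           # BitsPerSample
      tiff_entry(259L, 3L, 1L, 1L),            # Compression: none
      tiff_entry(262L, 3L, 1L, 1L),            # Photometric: BlackIsZero
      tiff_entry(273L, 4L, 1L, data_off[i]),   # StripOffsets
      tiff_entry(277L, 3L, 1L, 1L),            # SamplesPerPixel
      tiff_entry(278L, 4L, 1L, heights[i]),    # RowsPerStrip
      tiff_entry(279L, 4L, 1L, sizes[i]),      # StripByteCounts
      tiff_entry(339L, 3L, 1L, 3L),            # SampleFormat: IEEE float
      u32(if (i < n) ifd_off[i + 1L] else 0L)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x49L, 0x49L))) {
    chr_stop("chromofied_data_error", "only little-endian TIFF is supported")
  }
  r16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                            endian = "little")
  r32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (r16() != 42L) chr_stop("chromofied_data_error", "not a TIFF file")
  off <- r32()
  out <- list()
  while (off != 0L) {
    seek(con, off)
    nent <- r16()
    tags <- list()
    for (i in seq_len(nent)) {
      tag <- r16(); type <- r16(); count <- r32()
      val <- if (type == 3L) { v <- r16(); r16(); v } else r32()
      tags[[as.character(tag)]] <- list(type = type, count = count, val = val)
    }
    nxt <- r32()
    g <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$val
    }
    w <- g(256L); h <- g(257L)
    if (!identical(g(258L, 32L), 32L) || !identical(g(339L, 3L), 3L) ||
        !identical(g(259L, 1L), 1L)) {
      chr_stop("chromofied_data_error",
               "only uncompressed 32-bit float TIFF is supported")
    }
    so <- tags[["273"]]
    if (so$count != 1L) {
      chr_stop("chromofied_data_error", "multi-strip TIFF is not supported")
    }
    seek(con, so$val)
    px <- readBin(con, "numeric", w * h, size = 4L, endian = "little")
    out[[length(out) + 1L]] <- matrix(px, h, w, byrow = TRUE)
    off <- nxt
  }
  out
}
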