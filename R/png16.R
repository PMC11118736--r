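# Minimal 16-bit grayscale PNG encoder.
#
# The CRAN 'png' package reads 16-bit PNGs but only ever *writes* 8-bit ones,
# and no other installed package emits 16-bit PNG, so the encoder side is done
# here by hand: one IHDR, one zlib-compressed IDAT (filter type 0 on every
# scanline), one IEND. Decoding always goes through png::readPNG.

# Table-driven CRC-32 (ISO 3309, polynomial 0xEDB88320) over a raw vector,
# returned as 4 big-endian bytes. R's bitwShiftR is a logical shift, so the
# usual unsigned algorithm carries over to R's signed 32-bit integers.
crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), poly)
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32_raw <- function(bytes) {
  crc <- -1L # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  writeBin(bitwXor(crc, -1L), raw(), size = 4L, endian = "big")
}

uint32_be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

# Adler-32 (RFC 1950), blocked so double-precision sums never lose integer
# exactness.
adler32_raw <- function(bytes) {
  a <- 1
  b <- 0
  d <- as.integer(bytes)
  n <- length(d)
  i <- 1L
  while (i <= n) {
    j <- min(i + 65535L, n)
    blk <- d[i:j]
    m <- length(blk)
    b <- (b + m * a + sum(blk * (m - seq_len(m) + 1))) %% 65521
    a <- (a + sum(blk)) %% 65521
    i <- j + 1L
  }
  uint32_be(b * 65536 + a)
}

# zlib stream (RFC 1950) for PNG IDAT. memCompress(type = "gzip") in this R
# build already emits an RFC 1950 zlib stream (0x78 0x9c header, Adler-32
# trailer); verify the header and fall back to hand-wrapping the deflate
# payload if a future build emits a true gzip container.
zlib_compress <- function(bytes) {
  gz <- memCompress(bytes, type = "gzip")
  if (identical(as.integer(gz[1:2]), c(120L, 156L))) return(gz)
  if (identical(as.integer(gz[1:3]), c(31L, 139L, 8L)) &&
      as.integer(gz[4]) == 0L) {
    deflated <- gz[11:(length(gz) - 8L)]
    return(c(as.raw(c(0x78, 0x9c)), deflated, adler32_raw(bytes)))
  }
  stop("unrecognized container from memCompress")
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, crc32_raw(body))
}

#' Write a 16-bit grayscale PNG
#'
#' Encodes an integer matrix as a single-channel, 16-bit-per-sample PNG.
#' Values must lie in `[0, 65535]`; they are stored exactly (no rescaling),
#' so a write/read round trip through [read_slice()] is pixel-identical.
#'
#' @param pixels Integer (or whole-number numeric) matrix, values in
#'   `[0, 65535]`. Rows are image rows (y), columns are image columns (x).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_slice()], [write_slice()]
#' @export
write_png16 <- function(pixels, path) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  px <- pixels
  storage.mode(px) <- "double"
  if (anyNA(px) || any(px < 0) || any(px > 65535) || any(px != floor(px))) {
    stop("pixel values must be whole numbers in [0, 65535]")
  }
  h <- nrow(px)
  w <- ncol(px)
  # IHDR: width, height, bit depth 16, color type 0 (grayscale),
  # compression 0, filter 0, interlace 0
  ihdr <- c(uint32_be(w), uint32_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  # scanlines: filter byte 0, then big-endian 16-bit samples
  hi <- t(px %/% 256)
  lo <- t(px %% 256)
  sl <- matrix(0, nrow = 1L + 2L * w, ncol = h)
  sl[2L * seq_len(w), ] <- hi
  sl[2L * seq_len(w) + 1L, ] <- lo
  idat <- zlib_compress(as.raw(as.vector(sl)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}
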