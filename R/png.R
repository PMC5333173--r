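# Minimal 8-bit PNG writer (gray / RGB / RGBA, no interlacing).  memCompress()
# already produces a complete zlib stream, so only chunk framing and CRC-32
# are needed here.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        }
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), tab[idx + 1L])
  }
  crc <- bitwXor(crc, -1L)
  # to unsigned double
  if (crc < 0) crc + 4294967296 else as.numeric(crc)
}

u32be <- function(x) as.raw(c((x %/% 16777216) %% 256, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

#' Write an image as 8-bit PNG
#'
#' @param img either a numeric array `h x w x c` with `c` in `{1, 3, 4}` and
#'   values in `[0, 1]`, or a logical/integer matrix (integers taken as
#'   `[0, 255]`).  Row 1 is the top of the image.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.logical(img)) img <- array(as.numeric(img), dim = c(dim(img), 1L))
  if (is.matrix(img)) {
    img <- if (is.integer(img)) array(img / 255, dim = c(dim(img), 1L))
           else array(img, dim = c(dim(img), 1L))
  }
  d <- dim(img)
  if (length(d) != 3L || !d[3] %in% c(1L, 3L, 4L))
    stop("'img' must be h x w x {1,3,4}")
  v <- pmin(pmax(img, 0), 1)
  h <- d[1]; w <- d[2]; nc <- d[3]
  bytes <- array(as.integer(round(v * 255)), dim = d)
  # row-major, channels interleaved, one filter-type-0 byte per row
  px <- aperm(bytes, c(3L, 2L, 1L))            # (channel, col, row)
  rows <- matrix(as.vector(px), nrow = nc * w) # one column per row of image
  scan <- as.raw(rbind(0L, rows))              # prepend filter byte
  color_type <- c(0L, NA, 2L, 6L)[nc]
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8L, color_type, 0L, 0L, 0L)))
  idat <- memCompress(as.raw(scan), type = "gzip")  # zlib stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
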