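# Minimal baseline TIFF codec: multi-page, grayscale, 8/16-bit, uncompressed.
# No TIFF package ships with the supported R library, so the subset of the
# format this package needs is implemented directly.  The reader accepts both
# byte orders and multi-strip files (enough to read what tifffile writes for
# small grayscale stacks); the writer emits little-endian single-strip pages.

# --- little helpers -------------------------------------------------------

u16le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

rd_uint <- function(buf, off, n, size, big) {
  # off: 0-based offset; returns numeric vector of n unsigned ints
  idx <- off + seq_len(n * size)
  b <- as.integer(buf[idx])
  m <- matrix(b, nrow = size)
  w <- if (big) 256^((size - 1):0) else 256^(0:(size - 1))
  as.numeric(colSums(m * w))
}

TIFF_TYPE_SIZE <- c(1, 1, 2, 4, 8)  # BYTE, ASCII, SHORT, LONG, RATIONAL

# --- writer ---------------------------------------------------------------

# pages: list of integer matrices (nrow = image height, row 1 = top row),
# all same dims; bits: 8 or 16; description: character scalar stored on the
# first page's ImageDescription tag.
tiff_write_gray <- function(path, pages, bits = 8L, description = "") {
  stopifnot(length(pages) >= 1L, bits %in% c(8L, 16L))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  for (p in pages) {
    if (nrow(p) != h || ncol(p) != w) stop("all pages must share one shape")
    if (any(p < 0) || any(p > 2^bits - 1)) stop("pixel values exceed bit depth")
  }
  desc_raw <- c(charToRaw(as.character(description)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  strip_len <- h * w * (bits %/% 8L)
  pad <- strip_len %% 2L

  desc_off <- 8L
  strip_off <- function(i) desc_off + length(desc_raw) + (i - 1L) * (strip_len + pad)
  ifd0_off <- strip_off(length(pages) + 1L)

  entry <- function(tag, type, count, value) {
    # value fits in 4 bytes for everything we write except the description
    size <- TIFF_TYPE_SIZE[type] * count
    val <- if (type == 3L && size <= 4) c(u16le(value), u16le(0L))[1:4]
           else u32le(value)
    c(u16le(tag), u16le(type), u32le(count), val)
  }

  n_pages <- length(pages)
  ifd_bytes <- function(i) {
    entries <- list(
      entry(256L, 4L, 1L, w),             # ImageWidth
      entry(257L, 4L, 1L, h),             # ImageLength
      entry(258L, 3L, 1L, bits),          # BitsPerSample
      entry(259L, 3L, 1L, 1L),            # Compression = none
      entry(262L, 3L, 1L, 1L)             # Photometric = BlackIsZero
    )
    if (i == 1L && length(desc_raw) > 0L)
      entries <- c(entries, list(entry(270L, 2L, length(desc_raw), desc_off)))
    entries <- c(entries, list(
      entry(273L, 4L, 1L, strip_off(i)),  # StripOffsets
      entry(277L, 3L, 1L, 1L),            # SamplesPerPixel
      entry(278L, 4L, 1L, h),             # RowsPerStrip
      entry(279L, 4L, 1L, strip_len)      # StripByteCounts
    ))
    entries
  }
  ifd_len <- function(i) 2L + 12L * length(ifd_bytes(i)) + 4L
  ifd_offs <- ifd0_off + c(0L, cumsum(vapply(seq_len(n_pages), ifd_len, numeric(1))))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(42L), u32le(ifd_offs[1])), con)
  writeBin(desc_raw, con)
  for (p in pages) {
    v <- as.vector(t(p))  # row-major: TIFF stores rows sequentially
    raw <- if (bits == 8L) as.raw(v)
           else as.raw(as.vector(rbind(v %% 256, v %/% 256)))
    if (pad) raw <- c(raw, as.raw(0L))
    writeBin(raw, con)
  }
  for (i in seq_len(n_pages)) {
    ents <- ifd_bytes(i)
    writeBin(u16le(length(ents)), con)
    for (e in ents) writeBin(e, con)
    nxt <- if (i < n_pages) ifd_offs[i + 1L] else 0L
    writeBin(u32le(nxt), con)
  }
  invisible(path)
}

# --- reader ---------------------------------------------------------------

# Returns list(pages = list of integer matrices (row 1 = top), bits,
# description).  Errors on compressed, tiled, color or float TIFFs.
tiff_read_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  buf <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(buf) < 8L) stop("not a TIFF file: ", path)
  order <- rawToChar(buf[1:2])
  big <- if (order == "MM") TRUE else if (order == "II") FALSE
         else stop("not a TIFF file: ", path)
  if (rd_uint(buf, 2, 1, 2, big) != 42) stop("not a TIFF file: ", path)

  pages <- list()
  bits_all <- integer(0)
  description <- ""
  ifd_off <- rd_uint(buf, 4, 1, 4, big)
  while (ifd_off != 0) {
    n_ent <- rd_uint(buf, ifd_off, 1, 2, big)
    tags <- list()
    for (k in seq_len(n_ent)) {
      e_off <- ifd_off + 2 + (k - 1) * 12
      tag <- rd_uint(buf, e_off, 1, 2, big)
      type <- rd_uint(buf, e_off + 2, 1, 2, big)
      count <- rd_uint(buf, e_off + 4, 1, 4, big)
      if (!type %in% 1:5) next  # skip exotic types
      size <- TIFF_TYPE_SIZE[type] * count
      val_off <- if (size <= 4) e_off + 8 else rd_uint(buf, e_off + 8, 1, 4, big)
      tags[[as.character(tag)]] <- list(type = type, count = count, off = val_off)
    }
    gv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      if (t$type == 2L) {
        r <- buf[t$off + seq_len(t$count)]
        return(rawToChar(r[r != as.raw(0L)]))
      }
      sz <- TIFF_TYPE_SIZE[t$type]
      if (t$type == 5L) {  # RATIONAL: numerator/denominator pairs
        v <- rd_uint(buf, t$off, t$count * 2, 4, big)
        return(v[seq(1, length(v), 2)] / v[seq(2, length(v), 2)])
      }
      rd_uint(buf, t$off, t$count, sz, big)
    }
    w <- gv(256); h <- gv(257)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    bits <- gv(258, 8)[1]
    if (!bits %in% c(8, 16)) stop("unsupported bit depth: ", bits)
    if (gv(259, 1) != 1) stop("compressed TIFF not supported")
    spp <- gv(277, 1)
    if (spp != 1) stop("only single-sample (grayscale) TIFF supported")
    sf <- gv(339, 1)
    if (any(sf != 1)) stop("only unsigned-integer TIFF supported")
    if (!is.null(tags[["322"]])) stop("tiled TIFF not supported")
    d <- gv(270)
    if (!is.null(d) && !nzchar(description)) description <- d
    offs <- gv(273); cnts <- gv(279)
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    if (is.null(cnts)) cnts <- h * w * (bits / 8)
    data <- do.call(c, lapply(seq_along(offs), function(i)
      buf[offs[i] + seq_len(cnts[i])]))
    need <- h * w * (bits / 8)
    if (length(data) < need) stop("truncated TIFF strip data")
    data <- data[seq_len(need)]
    v <- if (bits == 8) as.integer(data) else {
      b <- as.integer(data)
      lo <- b[seq(1, length(b), 2)]; hi <- b[seq(2, length(b), 2)]
      if (big) lo * 256L + hi else hi * 256L + lo
    }
    pages[[length(pages) + 1L]] <- matrix(v, nrow = h, byrow = TRUE)
    bits_all <- c(bits_all, as.integer(bits))
    ifd_off <- rd_uint(buf, ifd_off + 2 + n_ent * 12, 1, 4, big)
  }
  if (length(pages) == 0L) stop("TIFF file contains no pages")
  if (length(unique(bits_all)) != 1L)
    stop("mixed bit depths across pages are not supported")
  list(pages = pages, bits = bits_all[1], description = description)
}
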