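# Reading and writing multi-channel z-stacks as multi-page TIFF.
#
# Page layouts: "channel_major" stores all z-slices of channel 1, then all of
# channel 2, ...; "z_major" interleaves channels within each z position
# (z1ch1, z1ch2, ..., z2ch1, ...).  write_zstack() always emits channel-major
# and records the stack geometry in the ImageDescription so that
# read_zstack(path) round-trips with no further arguments.

#' Read a multi-channel z-stack from a multi-page TIFF
#'
#' @param path TIFF file path.
#' @param channels number of channels, or `NULL` to take it from the file's
#'   ImageDescription metadata (falling back to 1).
#' @param layout page ordering, `"channel_major"` or `"z_major"`; `NULL`
#'   takes it from metadata (falling back to channel-major).
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres; `NULL` takes it
#'   from metadata.  When neither is available the acquisition default
#'   `(0.4, 0.1, 0.1)` is used with a warning (the 0.4 um z-increment of a
#'   typical confocal z-stack acquisition and a plausible lateral pitch).
#' @param names,colors channel labels and display colors; `NULL` takes them
#'   from metadata or generates defaults.
#' @return An [multichannel_stack()].
#' @export
read_zstack <- function(path, channels = NULL, layout = NULL, spacing = NULL,
                        names = NULL, colors = NULL) {
  tf <- tiff_read_gray(path)
  meta <- parse_stack_description(tf$description)
  if (is.null(channels)) channels <- if (!is.null(meta$channels)) meta$channels else 1L
  channels <- as.integer(channels)
  if (channels < 1L) stop("'channels' must be >= 1")
  if (is.null(layout)) layout <- if (!is.null(meta$layout)) meta$layout else "channel_major"
  layout <- match.arg(layout, c("channel_major", "z_major"))
  n_pages <- length(tf$pages)
  if (n_pages %% channels != 0L)
    stop(sprintf("page count not divisible by channel count (%d pages, %d channels)",
                 n_pages, channels))
  if (is.null(spacing)) spacing <- meta$spacing
  if (is.null(spacing)) {
    spacing <- c(0.4, 0.1, 0.1)
    warning("no voxel spacing in file or arguments; defaulting to (0.4, 0.1, 0.1) um")
  }
  if (is.null(names)) names <- meta$names
  if (is.null(colors)) colors <- meta$colors
  nz <- n_pages %/% channels
  h <- nrow(tf$pages[[1]]); w <- ncol(tf$pages[[1]])
  page_idx <- function(ch, z) {
    if (layout == "channel_major") (ch - 1L) * nz + z else (z - 1L) * channels + ch
  }
  grids <- lapply(seq_len(channels), function(ch) {
    arr <- array(0L, dim = c(nz, h, w))
    for (z in seq_len(nz)) {
      pg <- tf$pages[[page_idx(ch, z)]]
      arr[z, , ] <- pg[h:1, , drop = FALSE]  # file row 1 (top) -> world y max
    }
    voxel_grid(arr, bit_depth = as.integer(tf$bits), spacing = spacing)
  })
  if (is.null(names)) names <- paste0("ch", seq_len(channels))
  if (is.null(colors)) colors <- default_channel_colors(channels)
  multichannel_stack(grids, names = names, colors = colors)
}

#' Write a multi-channel z-stack to a multi-page TIFF
#'
#' Pages are written z-major within channel-major blocks; voxel spacing,
#' channel count, layout, names and colors are stored as `key=value` lines in
#' the ImageDescription so [read_zstack()] inverts the write exactly.
#'
#' @param stack an [multichannel_stack()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "mc_stack"))
  d <- stack_dim(stack); sp <- stack_spacing(stack)
  desc <- paste0(
    "spacing_um=", paste(format(sp, digits = 15, trim = TRUE), collapse = ","), "\n",
    "channels=", length(stack$channels), "\n",
    "layout=channel_major\n",
    "names=", paste(stack$names, collapse = ","), "\n",
    "colors=", paste(stack$colors, collapse = ","))
  pages <- vector("list", length(stack$channels) * d[1])
  i <- 0L
  for (ch in stack$channels) {
    for (z in seq_len(d[1])) {
      i <- i + 1L
      pages[[i]] <- ch$values[z, d[2]:1, , drop = TRUE]  # world y max -> file row 1
    }
  }
  tiff_write_gray(path, pages, bits = stack_bit_depth(stack), description = desc)
  invisible(path)
}

parse_stack_description <- function(desc) {
  out <- list()
  if (is.null(desc) || !nzchar(desc)) return(out)
  for (line in strsplit(desc, "\n", fixed = TRUE)[[1]]) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "spacing_um") {
      sp <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (length(sp) == 3L && all(is.finite(sp))) out$spacing <- sp
    } else if (key == "channels") {
      out$channels <- as.integer(val)
    } else if (key == "layout") {
      if (val %in% c("channel_major", "z_major")) out$layout <- val
    } else if (key == "names") {
      out$names <- strsplit(val, ",")[[1]]
    } else if (key == "colors") {
      out$colors <- strsplit(val, ",")[[1]]
    }
  }
  out
}
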