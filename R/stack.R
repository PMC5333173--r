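#' Voxel grid
#'
#' A single-channel confocal volume: a 3-D array of non-negative integer
#' intensities indexed `(z, y, x)` together with its acquisition bit depth and
#' anisotropic voxel spacing.
#'
#' The world frame used throughout the package is left-handed with x pointing
#' right (grid columns), y pointing up (grid rows) and z pointing away from
#' the viewer (slice index).  Array index 1 along y is the *bottom* row in
#' world space; the flip between world y-up and image-file row order happens
#' exactly once, at TIFF I/O (see [read_zstack()]).
#'
#' @param values 3-D numeric array, dimensions `(nz, ny, nx)`, intensities in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth 8 or 16.
#' @param spacing numeric length-3 voxel spacing `(dz, dy, dx)` in micrometres.
#' @return An object of class `voxel_grid`.
#' @seealso [multichannel_stack()], [normalize_intensity()]
#' @export
voxel_grid <- function(values, bit_depth = 8L, spacing = c(0.4, 0.1, 0.1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array indexed (z, y, x)")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive numbers (dz, dy, dx)")
  if (any(dim(values) < 1L)) stop("grid must have at least one voxel per dimension")
  if (any(values < 0) || any(values > 2^bit_depth - 1))
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  structure(list(values = values, bit_depth = bit_depth, spacing = spacing),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), %d-bit, spacing %.3g/%.3g/%.3g um\n",
              d[1], d[2], d[3], x$bit_depth, x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Multi-channel z-stack
#'
#' Co-registered per-channel volumes sharing one grid shape and voxel spacing,
#' each with a label and an RGB display color (e.g. blue nuclei, red
#' mitochondrial DNA, green tubulin, magenta actin).
#'
#' @param channels list of [voxel_grid()] objects with identical shape,
#'   spacing and bit depth.
#' @param names character vector, one label per channel.
#' @param colors one R color per channel (name or "#RRGGBB").
#' @return An object of class `mc_stack`.
#' @export
multichannel_stack <- function(channels,
                               names = paste0("ch", seq_along(channels)),
                               colors = default_channel_colors(length(channels))) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("'channels' must be a non-empty list of voxel_grid objects")
  ok <- vapply(channels, inherits, logical(1), "voxel_grid")
  if (!all(ok)) stop("every channel must be a voxel_grid")
  d0 <- dim(channels[[1]]$values)
  sp0 <- channels[[1]]$spacing
  bd0 <- channels[[1]]$bit_depth
  for (ch in channels) {
    if (!identical(dim(ch$values), d0)) stop("all channels must share one grid shape")
    if (!isTRUE(all.equal(ch$spacing, sp0))) stop("all channels must share one voxel spacing")
    if (ch$bit_depth != bd0) stop("all channels must share one bit depth")
  }
  if (length(names) != length(channels)) stop("one name per channel required")
  if (length(colors) != length(channels)) stop("one color per channel required")
  structure(list(channels = channels, names = as.character(names),
                 colors = as.character(colors)),
            class = "mc_stack")
}

default_channel_colors <- function(n) {
  base <- c("#FF0000", "#00FF00", "#0000FF", "#FF00FF")
  rep_len(base, n)
}

#' @export
print.mc_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf("<mc_stack> %d channel(s), %d x %d x %d (z,y,x), %d-bit\n",
              length(x$channels), d[1], d[2], d[3], stack_bit_depth(x)))
  cat("  channels:", paste(sprintf("%s (%s)", x$names, x$colors), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname multichannel_stack
#' @param stack an `mc_stack`.
#' @export
stack_dim <- function(stack) dim(stack$channels[[1]]$values)

#' @rdname multichannel_stack
#' @export
stack_spacing <- function(stack) stack$channels[[1]]$spacing

#' @rdname multichannel_stack
#' @export
stack_bit_depth <- function(stack) stack$channels[[1]]$bit_depth

#' World-space extent of a stack
#'
#' Physical size `(Lx, Ly, Lz)` of the volume in micrometres; the volume
#' occupies `[0, Lx] x [0, Ly] x [0, Lz]` in world coordinates, with voxel
#' centers at `(i - 0.5) * d` along each axis.
#'
#' @param stack an `mc_stack`.
#' @export
stack_extent <- function(stack) {
  d <- stack_dim(stack); sp <- stack_spacing(stack)
  c(d[3] * sp[3], d[2] * sp[2], d[1] * sp[1])  # (Lx, Ly, Lz)
}

# Convert an R color to an RGB triple in [0,1].
col_to_rgb01 <- function(col) as.numeric(grDevices::col2rgb(col)) / 255

#' Normalize intensities to the unit interval
#'
#' Divides a grid's integer intensities by `2^bit_depth - 1`, the explicit
#' conversion expected by the renderer's transfer function.  Order-preserving.
#'
#' @param grid a [voxel_grid()].
#' @return A `unit_grid`: list with real `values` in `[0, 1]` and `spacing`.
#' @export
normalize_intensity <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  structure(list(values = grid$values / (2^grid$bit_depth - 1),
                 spacing = grid$spacing),
            class = "unit_grid")
}
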