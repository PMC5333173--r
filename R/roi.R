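# Region-of-interest shapes and rasterization.
#
# A shape is a canonical solid (axis-aligned box, z-axis cylinder, or a
# polygon prism drawn in the flattened x-y view) anchored at a center point,
# carrying one accumulated transform (per-axis scale, rotation about the
# center, translation).  Local coordinates map to world coordinates as
#   p = center + translation + R %*% (scale * q)
# i.e. scale, then rotate, then translate, all about the shape center.
# Rasterization reproduces the footprint-plus-z-interval mask model: a 2-D
# boolean footprint over (y, x) and inclusive front/back slice indices, with
# the footprint extruded over the z-interval.  All indices are 1-based.

identity_transform <- function() {
  list(translation = c(0, 0, 0), rotation = diag(3), scale = c(1, 1, 1))
}

new_roi_shape <- function(kind, center, params, transform = identity_transform()) {
  structure(list(kind = kind, center = center, params = params,
                 transform = transform),
            class = "roi_shape")
}

#' @export
print.roi_shape <- function(x, ...) {
  cat(sprintf("<roi_shape> %s at (%.3g, %.3g, %.3g), scale (%.3g, %.3g, %.3g)\n",
              x$kind, x$center[1], x$center[2], x$center[3],
              x$transform$scale[1], x$transform$scale[2], x$transform$scale[3]))
  invisible(x)
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues rotation about a unit axis, used for ROI manipulation in the
#' left-handed world frame (angles in degrees, positive sense given by the
#' axis direction and the frame's handedness).
#'
#' @param axis length-3 direction (normalized internally; must be nonzero).
#' @param angle_deg rotation angle in degrees.
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be nonzero")
  a <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Create a box ROI spanning the whole volume
#'
#' The box tool starts out including the entire sample and is then
#' transformed down to the region of interest.
#'
#' @param stack an [multichannel_stack()].
#' @return A `roi_shape` of kind `"box"` with identity transform.
#' @export
make_box_roi <- function(stack) {
  ext <- stack_extent(stack)  # (Lx, Ly, Lz)
  new_roi_shape("box", center = ext / 2, params = list(half = ext / 2))
}

#' Create a cylinder ROI spanning the whole volume
#'
#' Axis along world z through the volume center; radius half the smaller
#' lateral extent, length the full z extent.
#'
#' @param stack an [multichannel_stack()].
#' @return A `roi_shape` of kind `"cylinder"`.
#' @export
make_cylinder_roi <- function(stack) {
  ext <- stack_extent(stack)
  new_roi_shape("cylinder", center = ext / 2,
                params = list(radius = min(ext[1], ext[2]) / 2,
                              half_length = ext[3] / 2))
}

#' Create a freehand (polygon) ROI
#'
#' Vertices are drawn in the flattened, front-facing x-y view (orthographic;
#' the flattening step avoids parallax), in world units.  The polygon is
#' closed automatically and extruded over the full stack depth; the z extent
#' is then positioned by scaling/translating along z.
#'
#' @param vertices numeric n x 2 matrix of (x, y) vertices, n >= 3.
#' @param stack an [multichannel_stack()].
#' @return A `roi_shape` of kind `"freehand"`.
#' @export
make_freehand_roi <- function(vertices, stack) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("freehand ROI needs at least 3 (x, y) vertices")
  # drop an explicitly repeated closing vertex
  if (nrow(vertices) > 3L &&
      isTRUE(all.equal(vertices[1, ], vertices[nrow(vertices), ])))
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  v1 <- vertices[, 1] - vertices[1, 1]; v2 <- vertices[, 2] - vertices[1, 2]
  area2 <- sum(v1 * c(v2[-1], v2[1])) - sum(v2 * c(v1[-1], v1[1]))
  if (abs(area2) < 1e-12) stop("freehand vertices are collinear")
  ext <- stack_extent(stack)
  c2 <- colMeans(vertices)
  new_roi_shape("freehand",
                center = c(c2[1], c2[2], ext[3] / 2),
                params = list(vertices = sweep(vertices, 2, c2),
                              half_length = ext[3] / 2))
}

#' Transform an ROI
#'
#' Composes an interactive manipulation step with the shape's accumulated
#' transform: scale factors multiply per axis, the rotation is composed, and
#' translations add, all interpreted about the shape center (the same
#' parameter-space composition a handle-based UI applies).
#'
#' @param shape a `roi_shape`.
#' @param translation length-3 world translation.
#' @param rotation a 3x3 rotation matrix, e.g. from [rotation_axis_angle()],
#'   or `NULL` for none.
#' @param scale length-3 positive per-axis scale factors.
#' @export
transform_roi <- function(shape, translation = c(0, 0, 0), rotation = NULL,
                          scale = c(1, 1, 1)) {
  stopifnot(inherits(shape, "roi_shape"))
  scale <- rep_len(as.numeric(scale), 3L)
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("scale factors must be positive")
  tr <- shape$transform
  tr$scale <- tr$scale * scale
  if (!is.null(rotation)) {
    if (!is.matrix(rotation) || !identical(dim(rotation), c(3L, 3L)))
      stop("'rotation' must be a 3x3 matrix")
    tr$rotation <- rotation %*% tr$rotation
  }
  tr$translation <- tr$translation + rep_len(as.numeric(translation), 3L)
  shape$transform <- tr
  shape
}

#' Scale an ROI along one axis
#'
#' The independent per-axis scaling used to position a selection in depth:
#' multiplies that axis's scale factor only.
#'
#' @param shape a `roi_shape`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param factor positive scale factor.
#' @export
scale_roi_axis <- function(shape, axis = c("x", "y", "z"), factor) {
  axis <- match.arg(axis)
  if (!is.finite(factor) || factor <= 0) stop("'factor' must be positive")
  s <- c(1, 1, 1)
  s[match(axis, c("x", "y", "z"))] <- factor
  transform_roi(shape, scale = s)
}

# world points (n x 3, columns x/y/z) -> local canonical coordinates
roi_to_local <- function(shape, pts) {
  tr <- shape$transform
  shift <- shape$center + tr$translation
  q <- sweep(pts, 2, shift) %*% tr$rotation  # rows q^T = (p-shift)^T R = (R^-1 p)^T
  sweep(q, 2, tr$scale, "/")
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Containment of world points in the transformed shape (vectorized).
roi_contains <- function(shape, pts, eps = 1e-9) {
  q <- roi_to_local(shape, pts)
  switch(shape$kind,
    box = {
      h <- shape$params$half
      abs(q[, 1]) <= h[1] + eps & abs(q[, 2]) <= h[2] + eps &
        abs(q[, 3]) <= h[3] + eps
    },
    cylinder = {
      r <- shape$params$radius; hl <- shape$params$half_length
      (q[, 1]^2 + q[, 2]^2) <= r^2 + eps & abs(q[, 3]) <= hl + eps
    },
    freehand = {
      hl <- shape$params$half_length
      point_in_polygon(q[, 1], q[, 2], shape$params$vertices) &
        abs(q[, 3]) <= hl + eps
    },
    stop("unknown ROI kind: ", shape$kind))
}

# Exact world-z extent of the transformed shape.
roi_z_extent <- function(shape) {
  tr <- shape$transform
  M3 <- tr$rotation[3, ] * tr$scale  # world z of local q is cz+Tz + sum(M3*q)
  cz <- shape$center[3] + tr$translation[3]
  switch(shape$kind,
    box = {
      a <- sum(abs(M3) * shape$params$half)
      c(cz - a, cz + a)
    },
    cylinder = {
      a <- sqrt(M3[1]^2 + M3[2]^2) * shape$params$radius +
        abs(M3[3]) * shape$params$half_length
      c(cz - a, cz + a)
    },
    freehand = {
      v <- shape$params$vertices
      zz <- M3[1] * v[, 1] + M3[2] * v[, 2]
      a <- abs(M3[3]) * shape$params$half_length
      c(cz + min(zz) - a, cz + max(zz) + a)
    })
}

#' ROI mask constructor
#'
#' The mask representation produced by ROI selection: a 2-D boolean footprint
#' over (y, x) plus inclusive front and back z slice indices; the selected
#' voxels are the footprint extruded over `[z_front, z_back]`.  An empty mask
#' has an all-`FALSE` footprint and `NA` z positions.
#'
#' @param footprint logical `ny x nx` matrix (row 1 = world y minimum).
#' @param z_front,z_back inclusive 1-based slice indices (`NA` if empty).
#' @param dim grid dimensions `(nz, ny, nx)` the mask refers to.
#' @export
roi_mask <- function(footprint, z_front, z_back, dim) {
  dim <- as.integer(dim)
  stopifnot(is.logical(footprint), length(dim) == 3L)
  if (!identical(base::dim(footprint), dim[2:3]))
    stop("footprint shape must match the stack slice shape")
  empty <- !any(footprint) || is.na(z_front) || is.na(z_back)
  if (empty) {
    footprint[] <- FALSE
    z_front <- NA_integer_; z_back <- NA_integer_
  } else {
    z_front <- as.integer(z_front); z_back <- as.integer(z_back)
    if (z_front < 1L || z_back > dim[1] || z_front > z_back)
      stop("need 1 <= z_front <= z_back <= number of slices")
  }
  structure(list(footprint = footprint, z_front = z_front, z_back = z_back,
                 dim = dim),
            class = "roi_mask")
}

#' @rdname roi_mask
#' @param mask a `roi_mask`.
#' @export
roi_mask_is_empty <- function(mask) is.na(mask$z_front)

#' @export
print.roi_mask <- function(x, ...) {
  if (roi_mask_is_empty(x)) cat("<roi_mask> empty\n")
  else cat(sprintf("<roi_mask> %d footprint cells, z in [%d, %d] of %d slices\n",
                   sum(x$footprint), x$z_front, x$z_back, x$dim[1]))
  invisible(x)
}

#' Rasterize an ROI shape into a mask
#'
#' A footprint cell (y, x) is set when any voxel center along its z-column
#' lies inside the transformed shape; the z interval is the shape's exact
#' world-z extent clamped to the volume (slices whose centers fall inside it).
#' The 3-D selection is the footprint extruded over the z interval, which
#' over-covers tilted shapes by construction -- a faithful reproduction of
#' the footprint-plus-z-extent mask model.
#'
#' @param shape a `roi_shape`.
#' @param stack an [multichannel_stack()].
#' @return A [roi_mask()]; empty if the shape misses the volume.
#' @export
rasterize_roi <- function(shape, stack) {
  stopifnot(inherits(shape, "roi_shape"), inherits(stack, "mc_stack"))
  d <- stack_dim(stack); sp <- stack_spacing(stack)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  xs <- (seq_len(nx) - 0.5) * sp[3]
  ys <- (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[1]
  gx <- rep(xs, each = ny)   # column-major (y fastest) like an ny x nx matrix
  gy <- rep(ys, times = nx)
  fp <- rep(FALSE, ny * nx)
  zext <- roi_z_extent(shape)
  zin <- which(zs >= zext[1] - 1e-9 & zs <= zext[2] + 1e-9)
  for (z in (if (length(zin)) zs[zin] else zs)) {
    todo <- !fp
    if (!any(todo)) break
    pts <- cbind(gx[todo], gy[todo], z)
    fp[todo] <- roi_contains(shape, pts)
  }
  footprint <- matrix(fp, nrow = ny, ncol = nx)
  if (length(zin) == 0L) {
    # shape thinner than one slice: take the slice containing its midpoint,
    # if that lies inside the volume
    mid <- mean(zext)
    zi <- floor(mid / sp[1]) + 1
    if (mid >= 0 && mid <= nz * sp[1] && any(footprint))
      return(roi_mask(footprint, min(zi, nz), min(zi, nz), d))
    return(roi_mask(matrix(FALSE, ny, nx), NA, NA, d))
  }
  roi_mask(footprint, min(zin), max(zin), d)
}

#' Enumerate the voxels selected by a mask
#'
#' @param mask a [roi_mask()].
#' @return Integer matrix with columns `z`, `y`, `x` (1-based); the number of
#'   rows is `footprint count * z span`.  Zero rows for an empty mask.
#' @export
roi_voxel_indices <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (roi_mask_is_empty(mask))
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("z", "y", "x"))))
  yx <- which(mask$footprint, arr.ind = TRUE)
  zr <- mask$z_front:mask$z_back
  out <- cbind(z = rep(zr, each = nrow(yx)),
               y = rep(yx[, 1], times = length(zr)),
               x = rep(yx[, 2], times = length(zr)))
  storage.mode(out) <- "integer"
  out
}

# linear indices into a (nz, ny, nx) array for an index matrix (z, y, x)
voxel_linear_index <- function(idx, d) {
  idx[, 1] + d[1] * (idx[, 2] - 1) + d[1] * d[2] * (idx[, 3] - 1)
}

# full-volume mask
full_volume_mask <- function(stack) {
  d <- stack_dim(stack)
  roi_mask(matrix(TRUE, d[2], d[3]), 1L, d[1], d)
}

#' Serialize / deserialize an ROI shape as JSON
#'
#' @param shape a `roi_shape`.
#' @param path JSON file path.
#' @export
write_roi_json <- function(shape, path) {
  stopifnot(inherits(shape, "roi_shape"))
  obj <- list(kind = shape$kind, center = shape$center, params = shape$params,
              transform = list(translation = shape$transform$translation,
                               rotation = shape$transform$rotation,
                               scale = shape$transform$scale))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- obj$params
  if (!is.null(params$vertices)) params$vertices <- as.matrix(params$vertices)
  if (!is.null(params$half)) params$half <- as.numeric(params$half)
  rot <- obj$transform$rotation
  if (!is.matrix(rot)) rot <- matrix(unlist(rot), 3, 3, byrow = TRUE)
  tr <- list(translation = as.numeric(obj$transform$translation),
             rotation = rot,
             scale = as.numeric(obj$transform$scale))
  new_roi_shape(obj$kind, as.numeric(obj$center), params, tr)
}
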