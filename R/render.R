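# CPU direct volume rendering: perspective ray casting, view-aligned slice
# compositing, and pseudo-isosurface shading.
#
# Transfer function (one fixed choice for all modes): per channel, normalized
# intensity i below the channel's noise threshold maps to opacity 0; otherwise
# alpha_raw = i * channel_opacity * global_opacity and color = display color
# scaled by i.  Channels are merged per sample by over-compositing in channel
# order.  Opacity is corrected for the sampling distance as
#   alpha = 1 - (1 - alpha_raw)^(dt / dt_ref),   dt_ref = min voxel spacing,
# so renderings converge as the step shrinks and a homogeneous region has the
# exact closed-form pixel opacity 1 - (1 - alpha_raw)^(L / dt_ref).

#' Pinhole camera
#'
#' Left-handed world frame: x right, y up, z away from the viewer.  The
#' camera basis is `right = up x view`, `up' = view x right` (so a camera
#' looking down +z with +y up has +x to its right).  Rays pass through pixel
#' centers; image row 1 is the top of the image.
#'
#' @param position camera position (world units).
#' @param look_at point the camera looks at (alternative to `view`).
#' @param view view direction (ignored when `look_at` given).
#' @param up approximate up direction (must not be parallel to the view).
#' @param fov vertical field of view in degrees, in (0, 180).
#' @param width,height output image size in pixels.
#' @export
camera <- function(position, look_at = NULL, view = NULL, up = c(0, 1, 0),
                   fov = 40, width = 128L, height = 128L) {
  position <- as.numeric(position)
  if (!is.null(look_at)) view <- as.numeric(look_at) - position
  if (is.null(view)) stop("give either 'look_at' or 'view'")
  nv <- sqrt(sum(view^2))
  if (nv < 1e-12) stop("view direction must be nonzero")
  view <- view / nv
  up <- as.numeric(up)
  if (fov <= 0 || fov >= 180) stop("'fov' must be in (0, 180) degrees")
  if (width < 1 || height < 1) stop("image dimensions must be positive")
  right <- cross3(up, view)
  if (sqrt(sum(right^2)) < 1e-9) stop("'up' must not be parallel to the view direction")
  right <- right / sqrt(sum(right^2))
  upv <- cross3(view, right)
  structure(list(position = position, view = view, right = right, up = upv,
                 fov = fov, width = as.integer(width), height = as.integer(height)),
            class = "camera")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Render settings
#'
#' @param mode `"raycast"`, `"slices"` or `"isosurface"`.
#' @param step ray sampling distance as a fraction of the minimum voxel
#'   spacing (default 0.5).
#' @param slice_count number of view-aligned proxy planes (`NULL`: twice the
#'   largest grid dimension, resolved at render time).
#' @param global_opacity overall opacity in `[0, 1]`.
#' @param channel_opacity per-channel opacities in `[0, 1]` (recycled).
#' @param noise_low per-channel noise-filter threshold on the normalized
#'   intensity in `[0, 1]`; samples below it are fully transparent.
#' @param iso_value isosurface level on normalized intensity, in (0, 1).
#' @param early_stop_alpha accumulated-opacity cutoff for early ray
#'   termination, in (0, 1].
#' @param background background RGB (color name or numeric length 3).
#' @export
render_settings <- function(mode = c("raycast", "slices", "isosurface"),
                            step = 0.5, slice_count = NULL,
                            global_opacity = 1, channel_opacity = 1,
                            noise_low = 0, iso_value = 0.5,
                            early_stop_alpha = 0.99,
                            background = c(0, 0, 0)) {
  mode <- match.arg(mode)
  if (step <= 0) stop("'step' must be positive")
  if (!is.null(slice_count) && slice_count < 2) stop("'slice_count' must be >= 2")
  if (global_opacity < 0 || global_opacity > 1 ||
      any(channel_opacity < 0) || any(channel_opacity > 1))
    stop("opacities must be in [0, 1]")
  if (early_stop_alpha <= 0 || early_stop_alpha > 1)
    stop("'early_stop_alpha' must be in (0, 1]")
  if (is.character(background)) background <- col_to_rgb01(background)
  structure(list(mode = mode, step = step, slice_count = slice_count,
                 global_opacity = global_opacity,
                 channel_opacity = channel_opacity,
                 noise_low = noise_low, iso_value = iso_value,
                 early_stop_alpha = early_stop_alpha,
                 background = as.numeric(background)),
            class = "render_settings")
}

#' Trilinear interpolation of a scalar volume
#'
#' Samples a volume at arbitrary world positions by trilinear blending of the
#' eight surrounding voxel values, with clamp-to-edge at the borders.  Points
#' outside the volume bounds return 0.
#'
#' @param grid a `unit_grid` (from [normalize_intensity()]) or any list with
#'   3-D `values` `(z, y, x)` and `spacing` `(dz, dy, dx)`.
#' @param points numeric `n x 3` matrix of world positions, columns (x, y, z).
#' @return Numeric vector of n interpolated values.
#' @export
sample_trilinear <- function(grid, points) {
  arr <- grid$values; sp <- grid$spacing
  d <- dim(arr)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  outside <- x < 0 | x > nx * sp[3] | y < 0 | y > ny * sp[2] |
    z < 0 | z > nz * sp[1]
  fx <- pmin(pmax(x / sp[3] - 0.5, 0), nx - 1)
  fy <- pmin(pmax(y / sp[2] - 0.5, 0), ny - 1)
  fz <- pmin(pmax(z / sp[1] - 0.5, 0), nz - 1)
  i0 <- pmin(pmax(floor(fx), 0), max(nx - 2, 0)); tx <- pmin(fx - i0, 1)
  j0 <- pmin(pmax(floor(fy), 0), max(ny - 2, 0)); ty <- pmin(fy - j0, 1)
  k0 <- pmin(pmax(floor(fz), 0), max(nz - 2, 0)); tz <- pmin(fz - k0, 1)
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1); k1 <- pmin(k0 + 1, nz - 1)
  g <- function(k, j, i) arr[cbind(k + 1, j + 1, i + 1)]
  v <-
    g(k0, j0, i0) * (1 - tz) * (1 - ty) * (1 - tx) +
    g(k0, j0, i1) * (1 - tz) * (1 - ty) * tx +
    g(k0, j1, i0) * (1 - tz) * ty * (1 - tx) +
    g(k0, j1, i1) * (1 - tz) * ty * tx +
    g(k1, j0, i0) * tz * (1 - ty) * (1 - tx) +
    g(k1, j0, i1) * tz * (1 - ty) * tx +
    g(k1, j1, i0) * tz * ty * (1 - tx) +
    g(k1, j1, i1) * tz * ty * tx
  v[outside] <- 0
  v
}

#' Ray / axis-aligned box intersection (slab method)
#'
#' @param origin ray origin, length 3 (x, y, z).
#' @param direction ray direction, nonzero (need not be normalized).
#' @param lo,hi box corner bounds.
#' @return List with `hit` (logical), `t_near`, `t_far`; a ray misses iff
#'   `t_far < max(t_near, 0)`.
#' @export
ray_box_intersect <- function(origin, direction, lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  if (sqrt(sum(direction^2)) < 1e-15) stop("ray direction must be nonzero")
  r <- ray_box_slab(matrix(origin, 1), matrix(direction, 1), lo, hi)
  list(hit = r$t_far[1] >= max(r$t_near[1], 0),
       t_near = r$t_near[1], t_far = r$t_far[1])
}

# vectorized slab test: origins/dirs are n x 3
ray_box_slab <- function(origins, dirs, lo, hi) {
  n <- nrow(dirs)
  t_near <- rep(-Inf, n); t_far <- rep(Inf, n)
  for (ax in 1:3) {
    o <- origins[, ax]; dv <- dirs[, ax]
    zero <- abs(dv) < 1e-300
    inv <- 1 / dv
    t1 <- (lo[ax] - o) * inv; t2 <- (hi[ax] - o) * inv
    tmin <- pmin(t1, t2); tmax <- pmax(t1, t2)
    if (any(zero)) {
      inside <- o >= lo[ax] & o <= hi[ax]
      tmin[zero] <- ifelse(inside[zero], -Inf, Inf)
      tmax[zero] <- ifelse(inside[zero], Inf, -Inf)
    }
    t_near <- pmax(t_near, tmin); t_far <- pmin(t_far, tmax)
  }
  list(t_near = t_near, t_far = t_far)
}

#' Front-to-back compositing step
#'
#' Premultiplied "over" accumulation: given the accumulated RGBA (rgb
#' premultiplied by alpha) and one sample RGBA (rgb *not* premultiplied),
#' returns `C + (1 - A) * c * a` and `A + (1 - A) * a`.
#'
#' @param accum length-4 numeric, accumulated premultiplied (r, g, b, a).
#' @param sample length-4 numeric sample (r, g, b, a).
#' @export
composite_front_to_back <- function(accum, sample) {
  w <- (1 - accum[4]) * sample[4]
  c(accum[1:3] + w * sample[1:3], accum[4] + w)
}

# --- shared machinery -----------------------------------------------------

camera_ray_dirs <- function(cam) {
  th <- tan(cam$fov / 2 * pi / 180)
  aspect <- cam$width / cam$height
  cs <- (2 * (seq_len(cam$width) - 0.5) / cam$width - 1) * th * aspect
  rs <- (1 - 2 * (seq_len(cam$height) - 0.5) / cam$height) * th
  # vector index = r + (c-1)*H  (column-major H x W)
  u <- rep(cs, each = cam$height)
  v <- rep(rs, times = cam$width)
  dirs <- cbind(cam$view[1] + u * cam$right[1] + v * cam$up[1],
                cam$view[2] + u * cam$right[2] + v * cam$up[2],
                cam$view[3] + u * cam$right[3] + v * cam$up[3])
  dirs / sqrt(rowSums(dirs^2))
}

resolve_settings <- function(stack, settings) {
  nch <- length(stack$channels)
  s <- settings
  s$channel_opacity <- rep_len(s$channel_opacity, nch)
  s$noise_low <- rep_len(s$noise_low, nch)
  if (is.null(s$slice_count)) s$slice_count <- 2L * max(stack_dim(stack))
  s
}

# Evaluate the transfer function at world points for all channels, merging
# channels per sample by over-compositing in channel order.  dt: per-point
# sampling distance for opacity correction.  Returns premultiplied rgb (Cp)
# and alpha (A).
transfer_sample <- function(norm_grids, colors, settings, pts, dt, dt_ref) {
  n <- nrow(pts)
  Cp <- matrix(0, n, 3); A <- numeric(n)
  for (ci in seq_along(norm_grids)) {
    i <- sample_trilinear(norm_grids[[ci]], pts)
    a_raw <- ifelse(i < settings$noise_low[ci], 0,
                    i * settings$channel_opacity[ci] * settings$global_opacity)
    a <- 1 - (1 - a_raw)^(dt / dt_ref)
    w <- (1 - A) * a
    col <- colors[[ci]]
    Cp[, 1] <- Cp[, 1] + w * col[1] * i
    Cp[, 2] <- Cp[, 2] + w * col[2] * i
    Cp[, 3] <- Cp[, 3] + w * col[3] * i
    A <- A + w
  }
  list(Cp = Cp, A = A)
}

finish_image <- function(C, A, cam, background) {
  img <- array(0, dim = c(cam$height, cam$width, 4))
  for (k in 1:3) img[, , k] <- matrix(C[, k] + (1 - A) * background[k],
                                      cam$height, cam$width)
  img[, , 4] <- matrix(A, cam$height, cam$width)
  img <- pmin(pmax(img, 0), 1)
  structure(img, class = "rgba_image")
}

#' @export
print.rgba_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgba_image> %d x %d, alpha range [%.3f, %.3f]\n",
              d[2], d[1], min(x[, , 4]), max(x[, , 4])))
  invisible(x)
}

# --- renderers ------------------------------------------------------------

#' Render a volume by perspective ray casting
#'
#' Image-order rendering: for each pixel a ray is intersected with the
#' volume's bounding box, marched from entry to exit at the configured step,
#' samples are mapped through the transfer function and composited front to
#' back with early termination.  By construction rays start on the *faces* of
#' the bounding box: a camera inside the box sees only background (the
#' documented limitation of this mode; use [render_slices()] from within the
#' volume).
#'
#' @param stack an [multichannel_stack()].
#' @param cam a [camera()].
#' @param settings a [render_settings()].
#' @return An `rgba_image` (height x width x 4 array in `[0, 1]`).
#' @export
render_raycast <- function(stack, cam, settings = render_settings()) {
  settings <- resolve_settings(stack, settings)
  norm_grids <- lapply(stack$channels, normalize_intensity)
  colors <- lapply(stack$colors, col_to_rgb01)
  sp <- stack_spacing(stack)
  dt_ref <- min(sp)
  dt_nom <- settings$step * dt_ref
  ext <- stack_extent(stack)
  dirs <- camera_ray_dirs(cam)
  n <- nrow(dirs)
  origins <- matrix(cam$position, n, 3, byrow = TRUE)
  slab <- ray_box_slab(origins, dirs, c(0, 0, 0), ext)
  active0 <- slab$t_far >= slab$t_near & slab$t_near >= 0
  C <- matrix(0, n, 3); A <- numeric(n)
  if (any(active0)) {
    len <- pmax(slab$t_far - slab$t_near, 0)
    K <- pmax(1, ceiling(len / dt_nom))
    K[!active0] <- 0L
    dt_i <- ifelse(K > 0, len / pmax(K, 1), 0)
    maxK <- max(K)
    for (k in seq_len(maxK)) {
      act <- which(K >= k & A < settings$early_stop_alpha)
      if (length(act) == 0L) break
      t <- slab$t_near[act] + (k - 0.5) * dt_i[act]
      pts <- cbind(cam$position[1] + dirs[act, 1] * t,
                   cam$position[2] + dirs[act, 2] * t,
                   cam$position[3] + dirs[act, 3] * t)
      smp <- transfer_sample(norm_grids, colors, settings, pts, dt_i[act], dt_ref)
      w <- 1 - A[act]
      C[act, ] <- C[act, ] + w * smp$Cp
      A[act] <- A[act] + w * smp$A
    }
  }
  finish_image(C, A, cam, settings$background)
}

#' Render a volume by view-aligned slice compositing
#'
#' Object-order rendering: proxy planes perpendicular to the viewing
#' direction span the volume's depth range and are composited back to front
#' with the same transfer function as [render_raycast()].  Planes at or
#' behind the eye are skipped, so this mode still produces a visualization
#' when the camera is inside the volume.
#'
#' @inheritParams render_raycast
#' @export
render_slices <- function(stack, cam, settings = render_settings(mode = "slices")) {
  settings <- resolve_settings(stack, settings)
  norm_grids <- lapply(stack$channels, normalize_intensity)
  colors <- lapply(stack$colors, col_to_rgb01)
  sp <- stack_spacing(stack)
  dt_ref <- min(sp)
  ext <- stack_extent(stack)
  corners <- as.matrix(expand.grid(x = c(0, ext[1]), y = c(0, ext[2]),
                                   z = c(0, ext[3])))
  dvals <- as.numeric((corners - matrix(cam$position, 8, 3, byrow = TRUE)) %*% cam$view)
  dmax <- max(dvals); dmin <- max(min(dvals), 1e-9)
  dirs <- camera_ray_dirs(cam)
  n <- nrow(dirs)
  C <- matrix(rep(settings$background, each = n), n, 3)  # premult over opaque bg
  A <- numeric(n)
  if (dmax > dmin) {
    nsl <- settings$slice_count
    dd <- (dmax - dmin) / (nsl - 1)
    denom <- as.numeric(dirs %*% cam$view)  # > 0 for fov < 180
    for (dj in seq(dmax, dmin, length.out = nsl)) {
      t <- dj / denom
      ok <- which(t > 1e-9)
      if (length(ok) == 0L) next
      pts <- cbind(cam$position[1] + dirs[ok, 1] * t[ok],
                   cam$position[2] + dirs[ok, 2] * t[ok],
                   cam$position[3] + dirs[ok, 3] * t[ok])
      dt <- dd / denom[ok]
      smp <- transfer_sample(norm_grids, colors, settings, pts, dt, dt_ref)
      # back-to-front premultiplied over
      C[ok, ] <- smp$Cp + (1 - smp$A) * C[ok, ]
      A[ok] <- smp$A + (1 - smp$A) * A[ok]
    }
  }
  img <- array(0, dim = c(cam$height, cam$width, 4))
  for (k in 1:3) img[, , k] <- matrix(C[, k], cam$height, cam$width)
  img[, , 4] <- matrix(A, cam$height, cam$width)
  img <- pmin(pmax(img, 0), 1)
  structure(img, class = "rgba_image")
}

#' Render a pseudo-isosurface
#'
#' First-hit ray casting: each ray stops at the first sample whose
#' interpolated normalized intensity (maximum over channels) reaches
#' `iso_value`; the surface normal is the normalized central-difference
#' gradient there and the pixel is shaded with a Lambertian headlight term
#' `max(0, n . l)` in the color of the dominant channel.  Produces results
#' similar to a marching-cubes surface without extracting a mesh.
#'
#' @inheritParams render_raycast
#' @export
render_isosurface <- function(stack, cam,
                              settings = render_settings(mode = "isosurface")) {
  settings <- resolve_settings(stack, settings)
  if (settings$iso_value <= 0 || settings$iso_value >= 1)
    stop("'iso_value' must be in (0, 1)")
  norm_grids <- lapply(stack$channels, normalize_intensity)
  colors <- lapply(stack$colors, col_to_rgb01)
  sp <- stack_spacing(stack)
  dt_nom <- settings$step * min(sp)
  ext <- stack_extent(stack)
  dirs <- camera_ray_dirs(cam)
  n <- nrow(dirs)
  origins <- matrix(cam$position, n, 3, byrow = TRUE)
  slab <- ray_box_slab(origins, dirs, c(0, 0, 0), ext)
  active0 <- slab$t_far >= slab$t_near & slab$t_near >= 0
  hit <- rep(FALSE, n); t_hit <- numeric(n); ch_hit <- integer(n)
  if (any(active0)) {
    len <- pmax(slab$t_far - slab$t_near, 0)
    K <- pmax(1, ceiling(len / dt_nom)); K[!active0] <- 0L
    dt_i <- ifelse(K > 0, len / pmax(K, 1), 0)
    for (k in seq_len(max(K))) {
      act <- which(K >= k & !hit)
      if (length(act) == 0L) break
      t <- slab$t_near[act] + (k - 0.5) * dt_i[act]
      pts <- cbind(cam$position[1] + dirs[act, 1] * t,
                   cam$position[2] + dirs[act, 2] * t,
                   cam$position[3] + dirs[act, 3] * t)
      vals <- vapply(norm_grids, sample_trilinear, numeric(length(act)),
                     points = pts)
      if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(act))
      best <- max.col(vals, ties.method = "first")
      vmax <- vals[cbind(seq_along(act), best)]
      new <- vmax >= settings$iso_value
      if (any(new)) {
        ai <- act[new]
        hit[ai] <- TRUE; t_hit[ai] <- t[new]; ch_hit[ai] <- best[new]
      }
    }
  }
  C <- matrix(0, n, 3); A <- numeric(n)
  if (any(hit)) {
    for (ci in unique(ch_hit[hit])) {
      rays <- which(hit & ch_hit == ci)
      p <- cbind(cam$position[1] + dirs[rays, 1] * t_hit[rays],
                 cam$position[2] + dirs[rays, 2] * t_hit[rays],
                 cam$position[3] + dirs[rays, 3] * t_hit[rays])
      gx <- (sample_trilinear(norm_grids[[ci]], sweep(p, 2, c(sp[3], 0, 0), "+")) -
             sample_trilinear(norm_grids[[ci]], sweep(p, 2, c(sp[3], 0, 0), "-"))) / (2 * sp[3])
      gy <- (sample_trilinear(norm_grids[[ci]], sweep(p, 2, c(0, sp[2], 0), "+")) -
             sample_trilinear(norm_grids[[ci]], sweep(p, 2, c(0, sp[2], 0), "-"))) / (2 * sp[2])
      gz <- (sample_trilinear(norm_grids[[ci]], sweep(p, 2, c(0, 0, sp[1]), "+")) -
             sample_trilinear(norm_grids[[ci]], sweep(p, 2, c(0, 0, sp[1]), "-"))) / (2 * sp[1])
      gn <- sqrt(gx^2 + gy^2 + gz^2)
      # n = -g/|g| (outward), headlight l = -dir, so n . l = (g . dir)/|g|
      shade <- ifelse(gn < 1e-12, 1,
                      pmax(0, (gx * dirs[rays, 1] + gy * dirs[rays, 2] +
                               gz * dirs[rays, 3]) / gn))
      # the surface itself is opaque; the global opacity still applies so
      # that global_opacity = 0 blanks every render mode
      col <- colors[[ci]] * settings$global_opacity
      C[rays, 1] <- col[1] * shade
      C[rays, 2] <- col[2] * shade
      C[rays, 3] <- col[3] * shade
      A[rays] <- settings$global_opacity
    }
  }
  finish_image(C, A, cam, settings$background)
}

#' Render a volume (mode dispatch)
#'
#' @inheritParams render_raycast
#' @export
render_volume <- function(stack, cam, settings = render_settings()) {
  switch(settings$mode,
         raycast = render_raycast(stack, cam, settings),
         slices = render_slices(stack, cam, settings),
         isosurface = render_isosurface(stack, cam, settings),
         stop("unknown render mode: ", settings$mode))
}
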