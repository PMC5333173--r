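# Synthetic multi-channel phantoms with known colocalization ground truth.
#
# The phantom emulates the kind of structures a stained fibroblast sample
# shows under a confocal microscope -- compact fluorescent puncta (nuclear
# dots, mitochondrial DNA fragments) -- as isotropic Gaussian blobs on an
# integer intensity grid.  A controllable fraction of blob centers is shared
# between the first two channels (co-occurrence); shared-blob amplitudes in
# channel B follow slope * A-amplitude + Gaussian noise (correlation).
#
# Blob centers are drawn without replacement from a jittered lattice whose
# pitch guarantees a minimum center separation of 5 * sigma.  Together with
# the spherical 3 * sigma truncation of each blob this makes blobs
# non-interacting: no voxel inside one blob's truth region receives intensity
# from any other blob.  In the default noise-free world the measured
# percentage colocalization therefore equals the truth-mask percentage
# exactly; additive noise and amplitude noise are explicit opt-ins.

#' Phantom specification
#'
#' @param shape grid dimensions `(nz, ny, nx)`.
#' @param n_blobs blobs per channel.
#' @param sigma blob radius (Gaussian sigma) in voxels; blobs are truncated
#'   at `3 * sigma`.
#' @param amplitude length-2 range of peak blob amplitudes (native units).
#' @param overlap_fraction fraction of blob centers shared between channels
#'   1 and 2, in `[0, 1]`; the shared count is `round(overlap_fraction *
#'   n_blobs)`.
#' @param correlation slope linking a shared blob's channel-B amplitude to
#'   its channel-A amplitude.
#' @param cor_noise_sd Gaussian sd of the amplitude noise on that link.
#' @param noise_sd additive Gaussian intensity noise per voxel (0 = clean).
#' @param n_channels 2-4; channels beyond the pair get independent blobs.
#' @param bit_depth 8 or 16.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @param seed RNG seed; identical specs generate identical phantoms.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), n_blobs = 120, sigma = 1.5,
                         amplitude = c(150, 230), overlap_fraction = 0.5,
                         correlation = 1, cor_noise_sd = 0, noise_sd = 0,
                         n_channels = 2, bit_depth = 8,
                         spacing = c(0.4, 0.1, 0.1), seed = 1) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("'overlap_fraction' must be in [0, 1]")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (noise_sd < 0 || cor_noise_sd < 0) stop("noise sds must be >= 0")
  if (n_channels < 2 || n_channels > 4) stop("'n_channels' must be 2..4")
  structure(list(shape = as.integer(shape), n_blobs = as.integer(n_blobs),
                 sigma = sigma, amplitude = as.numeric(amplitude),
                 overlap_fraction = overlap_fraction,
                 correlation = correlation, cor_noise_sd = cor_noise_sd,
                 noise_sd = noise_sd, n_channels = as.integer(n_channels),
                 bit_depth = as.integer(bit_depth),
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# jittered-lattice candidate sites guaranteeing min separation 5 * sigma
phantom_sites <- function(shape, sigma, n_needed) {
  min_sep <- 5 * sigma
  jitter <- sigma / 3
  pitch <- min_sep + 2 * jitter
  counts <- pmax(floor(shape / pitch), 1L)  # per (nz, ny, nx)
  if (prod(counts) < n_needed)
    stop(sprintf("blobs cannot fit: %d lattice sites for %d blob centers %s",
                 prod(counts), n_needed,
                 "(reduce n_blobs or sigma, or enlarge the grid)"))
  ax <- function(n_sites, extent) {
    start <- (extent - (n_sites - 1) * pitch) / 2
    start + (seq_len(n_sites) - 1) * pitch
  }
  g <- expand.grid(z = ax(counts[1], shape[1]), y = ax(counts[2], shape[2]),
                   x = ax(counts[3], shape[3]))
  pick <- sample.int(nrow(g), n_needed)
  ctr <- as.matrix(g[pick, c("z", "y", "x")])
  ctr + matrix(stats::runif(3 * n_needed, -jitter, jitter), ncol = 3)
}

# add one truncated Gaussian blob (center in voxel coordinates) to arr
add_blob <- function(arr, center, sigma, amp) {
  d <- dim(arr)
  rng <- function(c0, n) max(1, floor(c0 + 0.5 - 3 * sigma)):min(n, ceiling(c0 + 0.5 + 3 * sigma))
  iz <- rng(center[1], d[1]); iy <- rng(center[2], d[2]); ix <- rng(center[3], d[3])
  dz2 <- (iz - 0.5 - center[1])^2
  dy2 <- (iy - 0.5 - center[2])^2
  dx2 <- (ix - 0.5 - center[3])^2
  d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  v <- amp * exp(-d2 / (2 * sigma^2))
  v[d2 > (3 * sigma)^2] <- 0
  arr[iz, iy, ix] <- arr[iz, iy, ix] + v
  arr
}

#' Generate a synthetic phantom stack with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (an [multichannel_stack()]) and `truth`, a
#'   `phantom_truth` holding the per-channel blob centers (voxel
#'   coordinates, rows `(z, y, x)`), the shared centers, the blob
#'   amplitudes, and `mask`: the ground-truth co-occurrence mask (voxels
#'   within `2 * sigma` of a shared center).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$shape
    n <- spec$n_blobs
    n_shared <- round(spec$overlap_fraction * n)
    n_extra <- (spec$n_channels - 2L) * n
    n_total <- n_shared + 2L * (n - n_shared) + n_extra
    ctr <- phantom_sites(d, spec$sigma, n_total)
    take <- function(k) {
      if (k == 0L) return(ctr[integer(0), , drop = FALSE])
      out <- ctr[seq_len(k), , drop = FALSE]
      ctr <<- ctr[-seq_len(k), , drop = FALSE]
      out
    }
    shared <- take(n_shared)
    a_only <- take(n - n_shared)
    b_only <- take(n - n_shared)
    amp <- function(k) stats::runif(k, spec$amplitude[1], spec$amplitude[2])
    amp_shared_a <- amp(n_shared)
    amp_shared_b <- spec$correlation * amp_shared_a +
      stats::rnorm(n_shared, 0, spec$cor_noise_sd)
    maxv <- 2^spec$bit_depth - 1
    amp_shared_b <- pmin(pmax(amp_shared_b, 0), maxv)
    amp_a <- amp(n - n_shared)
    amp_b <- amp(n - n_shared)

    render_channel <- function(centers, amps) {
      arr <- array(0, dim = d)
      for (i in seq_len(nrow(centers)))
        arr <- add_blob(arr, centers[i, ], spec$sigma, amps[i])
      arr
    }
    chA <- render_channel(rbind(shared, a_only), c(amp_shared_a, amp_a))
    chB <- render_channel(rbind(shared, b_only), c(amp_shared_b, amp_b))
    arrs <- list(chA, chB)
    centers <- list(rbind(shared, a_only), rbind(shared, b_only))
    for (e in seq_len(spec$n_channels - 2L)) {
      ce <- take(n)
      arrs[[2L + e]] <- render_channel(ce, amp(n))
      centers[[2L + e]] <- ce
    }
    quantize <- function(arr) {
      if (spec$noise_sd > 0)
        arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
      array(as.integer(pmin(pmax(round(arr), 0), maxv)), dim = d)
    }
    grids <- lapply(arrs, function(a)
      voxel_grid(quantize(a), bit_depth = spec$bit_depth, spacing = spec$spacing))
    stack <- multichannel_stack(grids)

    mask <- array(FALSE, dim = d)
    if (n_shared > 0) {
      r2 <- (2 * spec$sigma)^2
      for (i in seq_len(n_shared)) {
        c0 <- shared[i, ]
        rngs <- lapply(1:3, function(ax)
          max(1, floor(c0[ax] + 0.5 - 2 * spec$sigma)):
            min(d[ax], ceiling(c0[ax] + 0.5 + 2 * spec$sigma)))
        d2 <- outer(outer((rngs[[1]] - 0.5 - c0[1])^2,
                          (rngs[[2]] - 0.5 - c0[2])^2, "+"),
                    (rngs[[3]] - 0.5 - c0[3])^2, "+")
        mask[rngs[[1]], rngs[[2]], rngs[[3]]] <-
          mask[rngs[[1]], rngs[[2]], rngs[[3]]] | (d2 <= r2)
      }
    }
    truth <- structure(list(centers = centers, shared = shared,
                            amplitudes = list(a = c(amp_shared_a, amp_a),
                                              b = c(amp_shared_b, amp_b)),
                            mask = mask, spec = spec),
                       class = "phantom_truth")
    list(stack = stack, truth = truth)
  })
}

#' Ground-truth percentage colocalization of a phantom
#'
#' The truth-mask counting oracle: among ROI-free in-band voxels of one
#' channel, the percentage lying inside the ground-truth co-occurrence mask.
#'
#' @param stack,truth output of [generate_phantom()].
#' @param channel 1 (percentage for A) or 2 (for B).
#' @param low,high intensity band applied to that channel.
#' @export
phantom_truth_pct <- function(stack, truth, channel = 1, low, high = NULL) {
  if (is.null(high)) high <- 2^stack_bit_depth(stack) - 1
  v <- stack$channels[[channel]]$values
  in_band <- v >= low & v <= high
  if (!any(in_band)) return(NaN)
  100 * sum(in_band & truth$mask) / sum(in_band)
}

#' Deterministic linear-ramp channel pair
#'
#' Channel A ramps linearly along x over the full intensity range; channel B
#' is `slope * A + intercept`, clipped to the bit depth.  Useful for exact
#' checks of the correlation metrics (PCC affine invariance, MOC scale
#' invariance).
#'
#' @param shape grid dimensions `(nz, ny, nx)`.
#' @param slope,intercept the linear link from A to B.
#' @param bit_depth 8 or 16.
#' @param spacing voxel spacing `(dz, dy, dx)`.
#' @export
generate_ramp_pair <- function(shape = c(8, 8, 32), slope = 1, intercept = 0,
                               bit_depth = 8, spacing = c(0.4, 0.1, 0.1)) {
  shape <- as.integer(shape)
  maxv <- 2^bit_depth - 1
  ramp <- round(seq(0, maxv, length.out = shape[3]))
  A <- array(rep(ramp, each = shape[1] * shape[2]), dim = shape)
  B <- pmin(pmax(round(slope * A + intercept), 0), maxv)
  multichannel_stack(list(
    voxel_grid(A, bit_depth = bit_depth, spacing = spacing),
    voxel_grid(B, bit_depth = bit_depth, spacing = spacing)),
    names = c("rampA", "rampB"))
}
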