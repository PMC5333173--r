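# Threshold-based colocalization metrics and visualizations.
#
# Conventions, fixed once for the whole package:
# * A voxel is "colocalized" when both channels lie inside their [low, high]
#   intensity band (and the voxel is inside the ROI).  This mask drives the
#   percentage colocalization, n_coloc and all visual render modes.
# * Manders' M1/M2, MOC and PCC use only the low thresholds -- the low
#   threshold acts as a noise filter removing background voxels; the high
#   threshold participates only in the percentage metrics and the masks.
# * The "considered set" S for MOC and PCC is the union: ROI voxels at or
#   above the low threshold in either channel.  (An intersection choice would
#   bias PCC toward co-occurring voxels only; all-ROI would re-admit the
#   background the noise filter is meant to remove.)
# * Metrics with an empty denominator come back as NaN and are listed in the
#   result's `undefined` field instead of raising, so batch reports degrade
#   gracefully.

#' Colocalization parameters
#'
#' @param ch_a,ch_b indices of the two channels checked for overlap
#'   (1-based, distinct).
#' @param low_a,high_a,low_b,high_b intensity thresholds in native units,
#'   `0 <= low <= high <= 2^bit_depth - 1`.  `high_*` of `NULL` means the
#'   channel maximum.
#' @param render_mode one of `"overlay_white"` (superimpose colocalized
#'   voxels as white on the original sample), `"coloc_only_original"`,
#'   `"coloc_only_white"`, `"none"`.
#' @param coloc_opacity opacity of the colocalized voxels in `[0, 1]`.
#' @return An object of class `coloc_params`.
#' @export
coloc_params <- function(ch_a, ch_b, low_a = 0, high_a = NULL,
                         low_b = 0, high_b = NULL,
                         render_mode = c("overlay_white", "coloc_only_original",
                                         "coloc_only_white", "none"),
                         coloc_opacity = 1) {
  render_mode <- match.arg(render_mode)
  if (ch_a == ch_b) stop("'ch_a' and 'ch_b' must be distinct channels")
  if (coloc_opacity < 0 || coloc_opacity > 1)
    stop("'coloc_opacity' must be in [0, 1]")
  structure(list(ch_a = as.integer(ch_a), ch_b = as.integer(ch_b),
                 low_a = low_a, high_a = high_a,
                 low_b = low_b, high_b = high_b,
                 render_mode = render_mode, coloc_opacity = coloc_opacity),
            class = "coloc_params")
}

# Resolve thresholds against a stack and pull the two channels' intensities
# over the ROI voxel list.  Returns the working set for every metric.
coloc_sets <- function(stack, params, roi = NULL) {
  stopifnot(inherits(stack, "mc_stack"), inherits(params, "coloc_params"))
  nch <- length(stack$channels)
  if (params$ch_a > nch || params$ch_b > nch || params$ch_a < 1 || params$ch_b < 1)
    stop("channel index out of range")
  if (is.null(roi)) roi <- full_volume_mask(stack)
  stopifnot(inherits(roi, "roi_mask"))
  d <- stack_dim(stack)
  if (!identical(roi$dim, d)) stop("ROI mask shape does not match the stack")
  maxv <- 2^stack_bit_depth(stack) - 1
  high_a <- if (is.null(params$high_a)) maxv else params$high_a
  high_b <- if (is.null(params$high_b)) maxv else params$high_b
  for (th in list(c(params$low_a, high_a), c(params$low_b, high_b)))
    if (th[1] < 0 || th[1] > th[2] || th[2] > maxv)
      stop("need 0 <= low <= high <= 2^bit_depth - 1")
  idx <- roi_voxel_indices(roi)
  li <- voxel_linear_index(idx, d)
  list(A = stack$channels[[params$ch_a]]$values[li],
       B = stack$channels[[params$ch_b]]$values[li],
       low_a = params$low_a, high_a = high_a,
       low_b = params$low_b, high_b = high_b,
       idx = idx, li = li, d = d, n_roi = nrow(idx))
}

#' Colocalized-voxel mask
#'
#' A voxel is marked when it lies inside the ROI and both channels fall
#' inside their `[low, high]` band.
#'
#' @param stack an [multichannel_stack()].
#' @param params a [coloc_params()].
#' @param roi a [roi_mask()], or `NULL` for the whole volume.
#' @return Logical 3-D array `(nz, ny, nx)`.
#' @export
coloc_voxel_mask <- function(stack, params, roi = NULL) {
  s <- coloc_sets(stack, params, roi)
  sel <- s$A >= s$low_a & s$A <= s$high_a & s$B >= s$low_b & s$B <= s$high_b
  out <- array(FALSE, dim = s$d)
  out[s$li[sel]] <- TRUE
  out
}

#' Manders' colocalization coefficients M1 and M2
#'
#' `M1` is the fraction of channel-A intensity (over ROI voxels with
#' `A >= low_a`) found where channel B is also at or above its low threshold;
#' `M2` is the channel-swapped analogue.  Empty denominators give `NaN`,
#' flagged in the `"undefined"` attribute.
#'
#' @inheritParams coloc_voxel_mask
#' @return Named list `m1`, `m2`.
#' @export
manders_mcc <- function(stack, params, roi = NULL) {
  s <- coloc_sets(stack, params, roi)
  a_on <- s$A >= s$low_a; b_on <- s$B >= s$low_b
  den1 <- sum(s$A[a_on]); den2 <- sum(s$B[b_on])
  m1 <- if (den1 > 0) sum(s$A[a_on & b_on]) / den1 else NaN
  m2 <- if (den2 > 0) sum(s$B[a_on & b_on]) / den2 else NaN
  undef <- c("m1", "m2")[c(den1 <= 0, den2 <= 0)]
  structure(list(m1 = m1, m2 = m2), undefined = undef)
}

#' Manders' overlap coefficient
#'
#' Cosine-like overlap `sum(A*B) / sqrt(sum(A^2) * sum(B^2))` over the
#' considered set S (ROI voxels at or above the low threshold in either
#' channel).
#'
#' @inheritParams coloc_voxel_mask
#' @export
manders_moc <- function(stack, params, roi = NULL) {
  s <- coloc_sets(stack, params, roi)
  S <- s$A >= s$low_a | s$B >= s$low_b
  a <- s$A[S]; b <- s$B[S]
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den > 0) sum(a * b) / den
  else structure(NaN, undefined = "moc")
}

#' Pearson's correlation of voxel intensities
#'
#' Standard Pearson correlation of the paired intensities over the same
#' considered set S as [manders_moc()].  `NaN` (flagged) when S has fewer
#' than two voxels or either channel is constant on S.
#'
#' @inheritParams coloc_voxel_mask
#' @export
pearson_pcc <- function(stack, params, roi = NULL) {
  s <- coloc_sets(stack, params, roi)
  S <- s$A >= s$low_a | s$B >= s$low_b
  a <- s$A[S]; b <- s$B[S]
  if (length(a) < 2) return(structure(NaN, undefined = "pcc"))
  va <- sum((a - mean(a))^2); vb <- sum((b - mean(b))^2)
  if (va <= 0 || vb <= 0) return(structure(NaN, undefined = "pcc"))
  sum((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
}

#' Percentage colocalization
#'
#' Voxel-count based: `n_a` and `n_b` count ROI voxels inside each channel's
#' `[low, high]` band, `n_coloc` counts voxels inside both bands, and
#' `pct_a = 100 * n_coloc / n_a` (analogously `pct_b`).  `0/0` is `NaN`,
#' flagged.
#'
#' @inheritParams coloc_voxel_mask
#' @return Named list `pct_a`, `pct_b`, `n_coloc`, `n_a`, `n_b`.
#' @export
percent_colocalization <- function(stack, params, roi = NULL) {
  s <- coloc_sets(stack, params, roi)
  in_a <- s$A >= s$low_a & s$A <= s$high_a
  in_b <- s$B >= s$low_b & s$B <= s$high_b
  n_a <- sum(in_a); n_b <- sum(in_b); n_coloc <- sum(in_a & in_b)
  pct_a <- if (n_a > 0) 100 * n_coloc / n_a else NaN
  pct_b <- if (n_b > 0) 100 * n_coloc / n_b else NaN
  undef <- c("pct_a", "pct_b")[c(n_a == 0, n_b == 0)]
  structure(list(pct_a = pct_a, pct_b = pct_b,
                 n_coloc = n_coloc, n_a = n_a, n_b = n_b),
            undefined = undef)
}

#' Full colocalization report
#'
#' Computes all five metrics plus voxel counts in one pass.
#'
#' @inheritParams coloc_voxel_mask
#' @return A `coloc_result`: `m1`, `m2`, `moc`, `pcc`, `pct_a`, `pct_b`,
#'   `n_coloc`, `n_a`, `n_b`, `n_considered`, and `undefined`, a character
#'   vector naming any metric with an empty denominator.
#' @export
coloc_report <- function(stack, params, roi = NULL) {
  s <- coloc_sets(stack, params, roi)
  mcc <- manders_mcc(stack, params, roi)
  moc <- manders_moc(stack, params, roi)
  pcc <- pearson_pcc(stack, params, roi)
  pct <- percent_colocalization(stack, params, roi)
  undefined <- c(attr(mcc, "undefined"), attr(moc, "undefined"),
                 attr(pcc, "undefined"), attr(pct, "undefined"))
  structure(list(m1 = mcc$m1, m2 = mcc$m2, moc = as.numeric(moc),
                 pcc = as.numeric(pcc),
                 pct_a = pct$pct_a, pct_b = pct$pct_b,
                 n_coloc = pct$n_coloc, n_a = pct$n_a, n_b = pct$n_b,
                 n_considered = sum(s$A >= s$low_a | s$B >= s$low_b),
                 undefined = if (is.null(undefined)) character(0) else undefined),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result>\n")
  cat(sprintf("  M1 = %.4f  M2 = %.4f  MOC = %.4f  PCC = %.4f\n",
              x$m1, x$m2, x$moc, x$pcc))
  cat(sprintf("  pct_a = %.2f%%  pct_b = %.2f%%  (n_coloc %d, n_a %d, n_b %d, |S| %d)\n",
              x$pct_a, x$pct_b, x$n_coloc, x$n_a, x$n_b, x$n_considered))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Colocalization visualization volume
#'
#' Builds an RGBA volume (array `nz x ny x nx x 4`, components in `[0, 1]`)
#' in one of the four display modes: overlay the colocalized voxels as white
#' on the original sample, show only the colocalized voxels (original colors
#' or white), or show the sample with no colocalization marking.
#'
#' The base volume maps each channel's normalized intensity through its
#' display color additively (clamped); base alpha is the maximum normalized
#' channel intensity.
#'
#' @inheritParams coloc_voxel_mask
#' @return Numeric array `nz x ny x nx x 4`, class `rgba_volume`.
#' @export
colocalization_volume <- function(stack, params, roi = NULL) {
  d <- stack_dim(stack)
  maxv <- 2^stack_bit_depth(stack) - 1
  rgb_cols <- lapply(stack$colors, col_to_rgb01)
  base <- array(0, dim = c(d, 4))
  alpha <- array(0, dim = d)
  for (i in seq_along(stack$channels)) {
    norm <- stack$channels[[i]]$values / maxv
    for (k in 1:3) base[, , , k] <- base[, , , k] + rgb_cols[[i]][k] * norm
    alpha <- pmax(alpha, norm)
  }
  base[, , , 1:3] <- pmin(base[, , , 1:3], 1)
  base[, , , 4] <- alpha
  cmask <- coloc_voxel_mask(stack, params, roi)
  op <- params$coloc_opacity
  out <- base
  mode <- params$render_mode
  if (mode == "none") {
    # unchanged
  } else if (mode == "overlay_white") {
    for (k in 1:3) {
      plane <- out[, , , k]
      plane[cmask] <- (1 - op) * plane[cmask] + op
      out[, , , k] <- plane
    }
    a <- out[, , , 4]; a[cmask] <- pmax(a[cmask], op); out[, , , 4] <- a
  } else if (mode == "coloc_only_original") {
    for (k in 1:4) {
      plane <- out[, , , k]; plane[!cmask] <- 0; out[, , , k] <- plane
    }
  } else if (mode == "coloc_only_white") {
    out[] <- 0
    for (k in 1:3) {
      plane <- out[, , , k]; plane[cmask] <- 1; out[, , , k] <- plane
    }
    a <- out[, , , 4]; a[cmask] <- op; out[, , , 4] <- a
  }
  structure(out, class = "rgba_volume")
}

#' 2-D intensity scatter histogram (fluorogram)
#'
#' Bins the paired `(A, B)` intensities of the considered set S into a
#' `bins x bins` equal-width grid over `range` (default the full bit-depth
#' range).  Row index = channel-A bin, column index = channel-B bin; the
#' total count equals `|S|`.
#'
#' @inheritParams coloc_voxel_mask
#' @param bins number of bins per axis, `>= 2`.
#' @param range intensity range covered by the bins, default
#'   `c(0, 2^bit_depth - 1)`.
#' @export
scatter_histogram <- function(stack, params, roi = NULL, bins = 64L,
                              range = NULL) {
  bins <- as.integer(bins)
  if (bins < 2L) stop("'bins' must be >= 2")
  s <- coloc_sets(stack, params, roi)
  if (is.null(range)) range <- c(0, 2^stack_bit_depth(stack) - 1)
  S <- s$A >= s$low_a | s$B >= s$low_b
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  ia <- findInterval(s$A[S], breaks, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(s$B[S], breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- matrix(0L, bins, bins)
  if (any(S)) {
    t <- table(factor(ia, levels = seq_len(bins)),
               factor(ib, levels = seq_len(bins)))
    h <- matrix(as.integer(t), bins, bins)
  }
  structure(h, breaks = breaks)
}

#' Pseudo-colored scatter plot image
#'
#' Maps histogram counts through a colormap: counts are normalized by the
#' maximum (optionally after a `log1p` transform) and looked up in an
#' `hcl.colors` palette; zero-count bins map to the background color.
#'
#' @param hist count matrix from [scatter_histogram()].
#' @param colormap an `hcl.colors` palette name (e.g. `"viridis"`).
#' @param log_scale logical; apply `log1p` before normalizing.
#' @param background background color for empty bins.
#' @return Numeric array `nrow x ncol x 3` in `[0, 1]`; attribute `"norm"`
#'   holds the normalized values used for the lookup.
#' @export
pseudocolor_scatter <- function(hist, colormap = "viridis", log_scale = FALSE,
                                background = "black") {
  if (any(hist < 0)) stop("histogram counts must be non-negative")
  pal <- grDevices::hcl.colors(256L, palette = colormap)  # errors on unknown name
  v <- if (log_scale) log1p(hist) else hist
  mx <- max(v)
  norm <- if (mx > 0) v / mx else v * 0
  img <- array(0, dim = c(nrow(hist), ncol(hist), 3L))
  bg <- col_to_rgb01(background)
  idx <- 1L + as.integer(round(norm * 255))
  cols <- t(grDevices::col2rgb(pal[idx])) / 255
  zero <- as.vector(hist == 0)
  for (k in 1:3) {
    plane <- cols[, k]
    plane[zero] <- bg[k]
    img[, , k] <- matrix(plane, nrow(hist), ncol(hist))
  }
  structure(img, norm = norm)
}
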