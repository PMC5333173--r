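# Independent reference implementations ("oracles") used across the suite.
# These deliberately avoid the package's vectorized code paths: plain scalar
# loops and naive formulas only.

# Wrap two intensity arrays (same dims) as a 2-channel stack.
make_ab_stack <- function(A, B, bit_depth = 8L, spacing = c(0.4, 0.1, 0.1)) {
  multichannel_stack(list(
    voxel_grid(A, bit_depth = bit_depth, spacing = spacing),
    voxel_grid(B, bit_depth = bit_depth, spacing = spacing)))
}

random_ab_stack <- function(dims, bit_depth = 8L, p_zero = 0.3) {
  maxv <- 2^bit_depth - 1
  n <- prod(dims)
  mk <- function() {
    v <- sample.int(maxv + 1L, n, replace = TRUE) - 1L
    v[stats::runif(n) < p_zero] <- 0L
    array(v, dim = dims)
  }
  make_ab_stack(mk(), mk(), bit_depth = bit_depth)
}

# Naive triple-loop colocalization metrics over an optional ROI mask.
ref_coloc_metrics <- function(stack, low_a, high_a, low_b, high_b, roi = NULL) {
  A <- stack$channels[[1]]$values
  B <- stack$channels[[2]]$values
  d <- dim(A)
  in_roi <- function(z, y, x) {
    if (is.null(roi)) return(TRUE)
    if (roi_mask_is_empty(roi)) return(FALSE)
    z >= roi$z_front && z <= roi$z_back && roi$footprint[y, x]
  }
  sumA_on <- 0; sumA_both <- 0; sumB_on <- 0; sumB_both <- 0
  sAB <- 0; sA2 <- 0; sB2 <- 0
  n_a <- 0L; n_b <- 0L; n_coloc <- 0L
  av <- c(); bv <- c()
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!in_roi(z, y, x)) next
    a <- A[z, y, x]; b <- B[z, y, x]
    a_on <- a >= low_a; b_on <- b >= low_b
    if (a_on) sumA_on <- sumA_on + a
    if (b_on) sumB_on <- sumB_on + b
    if (a_on && b_on) { sumA_both <- sumA_both + a; sumB_both <- sumB_both + b }
    if (a_on || b_on) {
      sAB <- sAB + a * b; sA2 <- sA2 + a^2; sB2 <- sB2 + b^2
      av <- c(av, a); bv <- c(bv, b)
    }
    ina <- a >= low_a && a <= high_a
    inb <- b >= low_b && b <= high_b
    if (ina) n_a <- n_a + 1L
    if (inb) n_b <- n_b + 1L
    if (ina && inb) n_coloc <- n_coloc + 1L
  }
  pcc <- if (length(av) >= 2 && stats::sd(av) > 0 && stats::sd(bv) > 0)
    sum((av - mean(av)) * (bv - mean(bv))) /
      sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2)) else NaN
  list(m1 = if (sumA_on > 0) sumA_both / sumA_on else NaN,
       m2 = if (sumB_on > 0) sumB_both / sumB_on else NaN,
       moc = if (sA2 > 0 && sB2 > 0) sAB / sqrt(sA2 * sB2) else NaN,
       pcc = pcc,
       pct_a = if (n_a > 0) 100 * n_coloc / n_a else NaN,
       pct_b = if (n_b > 0) 100 * n_coloc / n_b else NaN,
       n_coloc = n_coloc, n_a = n_a, n_b = n_b,
       n_considered = length(av))
}

# Scalar even-odd point-in-polygon (crossing number), one point at a time.
oracle_pip <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- verts[i, 2]; yj <- verts[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- verts[i, 1] + (py - yi) / (yj - yi) * (verts[j, 1] - verts[i, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Scalar containment of one world point in a transformed ROI shape,
# independent route: explicit matrix inverse via solve().
oracle_roi_contains <- function(shape, p) {
  tr <- shape$transform
  q <- solve(tr$rotation, p - shape$center - tr$translation) / tr$scale
  switch(shape$kind,
    box = all(abs(q) <= shape$params$half + 1e-9),
    cylinder = q[1]^2 + q[2]^2 <= shape$params$radius^2 + 1e-9 &&
      abs(q[3]) <= shape$params$half_length + 1e-9,
    freehand = oracle_pip(q[1], q[2], shape$params$vertices) &&
      abs(q[3]) <= shape$params$half_length + 1e-9)
}

# Exhaustive 3-D mask from per-voxel-center containment (the footprint is
# the any-z projection; the z-interval the slice range touched).
oracle_rasterize <- function(shape, stack) {
  d <- stack_dim(stack); sp <- stack_spacing(stack)
  arr <- array(FALSE, dim = d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    arr[z, y, x] <- oracle_roi_contains(
      shape, c((x - 0.5) * sp[3], (y - 0.5) * sp[2], (z - 0.5) * sp[1]))
  arr
}

# Back-to-front "over" composition of a sample list, each c(r, g, b, a)
# non-premultiplied; returns premultiplied accumulated c(rgb, a).
oracle_back_to_front <- function(samples) {
  C <- c(0, 0, 0); A <- 0
  for (s in rev(samples)) {
    C <- s[1:3] * s[4] + (1 - s[4]) * C
    A <- s[4] + (1 - s[4]) * A
  }
  c(C, A)
}

# Spearman rank correlation without ties handling (inputs are means).
spearman_rho <- function(x, y) stats::cor(rank(x), rank(y))

local_tmp <- function(ext = "") {
  tempfile(pattern = "coloc3d-test-", fileext = ext)
}
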