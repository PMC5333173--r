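# The four-voxel worked example used throughout: A = (4,2,0,1),
# B = (0,2,4,1), low = 1, high = 4.  Expected values were evaluated by hand:
# M1 = M2 = 3/7, MOC = 5/21, PCC = -7.25/8.75, n_a = n_b = 3, n_coloc = 2.
hand_example <- function() {
  st <- make_ab_stack(array(c(4L, 2L, 0L, 1L), c(4, 1, 1)),
                      array(c(0L, 2L, 4L, 1L), c(4, 1, 1)))
  list(stack = st,
       params = coloc_params(1, 2, low_a = 1, high_a = 4, low_b = 1, high_b = 4))
}

test_that("hand example reproduces all metrics exactly", {
  h <- hand_example()
  r <- coloc_report(h$stack, h$params)
  expect_equal(r$m1, 3 / 7, tolerance = 1e-14)
  expect_equal(r$m2, 3 / 7, tolerance = 1e-14)
  expect_equal(r$moc, 5 / 21, tolerance = 1e-14)
  expect_equal(r$pcc, -7.25 / 8.75, tolerance = 1e-14)
  expect_identical(c(r$n_a, r$n_b, r$n_coloc), c(3L, 3L, 2L))
  expect_equal(r$pct_a, 100 * 2 / 3, tolerance = 1e-14)
  expect_equal(r$pct_b, 100 * 2 / 3, tolerance = 1e-14)
  expect_identical(r$n_considered, 4L)
  expect_length(r$undefined, 0)
})

test_that("coloc_voxel_mask marks exactly the in-band voxels", {
  h <- hand_example()
  m <- coloc_voxel_mask(h$stack, h$params)
  expect_identical(as.vector(m), c(FALSE, TRUE, FALSE, TRUE))
  # identical channels, low = 1: mask reduces to A >= 1
  A <- array(c(0L, 3L, 7L, 0L, 2L, 9L), c(6, 1, 1))
  st <- make_ab_stack(A, A)
  m2 <- coloc_voxel_mask(st, coloc_params(1, 2, low_a = 1, low_b = 1))
  expect_identical(as.vector(m2), as.vector(A >= 1))
  # disjoint supports
  st3 <- make_ab_stack(array(c(5L, 0L), c(2, 1, 1)),
                       array(c(0L, 5L), c(2, 1, 1)))
  expect_false(any(coloc_voxel_mask(st3, coloc_params(1, 2, low_a = 1, low_b = 1))))
})

test_that("metric limit cases: identical, proportional, disjoint, undefined", {
  set.seed(11)
  A <- array(sample.int(200, 4^3, TRUE), c(4, 4, 4))
  st <- make_ab_stack(A, A)
  p <- coloc_params(1, 2, low_a = 1, low_b = 1)
  r <- coloc_report(st, p)
  expect_equal(r$m1, 1); expect_equal(r$m2, 1)
  expect_equal(r$moc, 1, tolerance = 1e-14)
  expect_equal(r$pcc, 1, tolerance = 1e-14)
  expect_equal(r$pct_a, 100); expect_equal(r$pct_b, 100)

  # B = A/2 on common support: MOC is scale-invariant, M1 stays 1
  Ae <- 2L * array(sample.int(100, 4^3, TRUE), c(4, 4, 4))
  stp <- make_ab_stack(Ae, Ae %/% 2L, bit_depth = 8L)
  rp <- coloc_report(stp, p)
  expect_equal(rp$moc, 1, tolerance = 1e-14)
  expect_equal(rp$m1, 1)

  # disjoint supports: co-occurrence metrics are zero
  st2 <- make_ab_stack(array(c(9L, 0L, 8L, 0L), c(4, 1, 1)),
                       array(c(0L, 7L, 0L, 6L), c(4, 1, 1)))
  r2 <- coloc_report(st2, p)
  expect_identical(c(r2$m1, r2$m2, r2$moc), c(0, 0, 0))
  expect_identical(r2$n_coloc, 0L)
  expect_identical(c(r2$pct_a, r2$pct_b), c(0, 0))

  # empty denominators are flagged NaN, not errors
  z <- array(0L, c(2, 2, 2))
  rz <- coloc_report(make_ab_stack(z, z), coloc_params(1, 2, low_a = 1, low_b = 1))
  expect_true(is.nan(rz$m1) && is.nan(rz$moc) && is.nan(rz$pcc))
  expect_setequal(rz$undefined, c("m1", "m2", "moc", "pcc", "pct_a", "pct_b"))
})

test_that("PCC is affine-invariant and MOC scale-invariant on exact ramps", {
  # integer-exact: A = 0..100 along x, B = 2A + 3 (no clipping, no rounding)
  A <- array(rep(0:100, each = 4), c(2, 2, 101))
  st <- make_ab_stack(A, 2L * A + 3L)
  p <- coloc_params(1, 2, low_a = 0, low_b = 0)
  expect_equal(pearson_pcc(st, p), 1, tolerance = 1e-14)
  stn <- make_ab_stack(A, 203L - 2L * A)   # negative slope
  expect_equal(pearson_pcc(stn, p), -1, tolerance = 1e-14)
  sts <- make_ab_stack(2L * A, A)          # B = A/2
  expect_equal(as.numeric(manders_moc(sts, p)), 1, tolerance = 1e-14)
})

test_that("all metrics agree with the naive triple-loop reference", {
  set.seed(99)
  for (rep in 1:8) {
    dims <- sample(3:10, 3, replace = TRUE)
    st <- random_ab_stack(dims)
    low_a <- sample(0:120, 1); low_b <- sample(0:120, 1)
    high_a <- sample(150:255, 1); high_b <- sample(150:255, 1)
    p <- coloc_params(1, 2, low_a, high_a, low_b, high_b)
    ref <- ref_coloc_metrics(st, low_a, high_a, low_b, high_b)
    got <- coloc_report(st, p)
    for (f in c("m1", "m2", "moc", "pcc", "pct_a", "pct_b"))
      expect_equal(got[[f]], ref[[f]], tolerance = 1e-12, label = f)
    for (f in c("n_coloc", "n_a", "n_b", "n_considered"))
      expect_identical(as.integer(got[[f]]), as.integer(ref[[f]]), label = f)
  }
})

test_that("metrics restricted to a box ROI equal metrics on the cropped stack", {
  set.seed(21)
  st <- random_ab_stack(c(8L, 12L, 12L))
  bx <- transform_roi(make_box_roi(st), scale = c(0.5, 0.5, 0.5))
  m <- rasterize_roi(bx, st)
  p <- coloc_params(1, 2, low_a = 10, low_b = 15)
  r_roi <- coloc_report(st, p, m)
  idx <- roi_voxel_indices(m)
  zr <- range(idx[, 1]); yr <- range(idx[, 2]); xr <- range(idx[, 3])
  crop <- function(v) v[zr[1]:zr[2], yr[1]:yr[2], xr[1]:xr[2], drop = FALSE]
  st_c <- make_ab_stack(crop(st$channels[[1]]$values),
                        crop(st$channels[[2]]$values))
  r_crop <- coloc_report(st_c, p)
  for (f in c("m1", "m2", "moc", "pcc", "pct_a", "pct_b", "n_coloc"))
    expect_equal(r_roi[[f]], r_crop[[f]], tolerance = 1e-12, label = f)
})

test_that("n_coloc is monotone in the thresholds", {
  set.seed(33)
  st <- random_ab_stack(c(6L, 8L, 8L))
  n_at <- function(lo, hi) {
    percent_colocalization(st, coloc_params(1, 2, lo, hi, lo, hi))$n_coloc
  }
  lows <- c(0, 20, 60, 120); highs <- c(255, 200, 150)
  for (i in seq_len(length(lows) - 1))
    expect_gte(n_at(lows[i], 255), n_at(lows[i + 1], 255))
  for (i in seq_len(length(highs) - 1))
    expect_gte(n_at(0, highs[i]), n_at(0, highs[i + 1]))
})

test_that("colocalization volume implements the four display modes", {
  h <- hand_example()
  base <- colocalization_volume(h$stack, h$params)  # overlay_white default
  cmask <- coloc_voxel_mask(h$stack, h$params)

  p_none <- h$params; p_none$render_mode <- "none"
  v_none <- colocalization_volume(h$stack, p_none)
  # mode none leaves the base volume untouched: voxel 1 has A=4 (red), B=0
  expect_equal(as.vector(v_none[1, 1, 1, ]), c(4 / 255, 0, 0, 4 / 255))

  # overlay: exactly the colocalized voxels are white at full opacity
  for (k in 1:3) {
    plane <- base[, , , k]
    expect_true(all(plane[cmask] == 1))
  }
  expect_false(all(base[1, 1, 1, 1:3] == 1))  # voxel 1 not colocalized

  p_w <- h$params; p_w$render_mode <- "coloc_only_white"
  v_w <- colocalization_volume(h$stack, p_w)
  expect_true(all(v_w[, , , 4][!cmask] == 0))
  expect_true(all(v_w[, , , 1][cmask] == 1))

  p_o <- h$params; p_o$render_mode <- "coloc_only_original"
  v_o <- colocalization_volume(h$stack, p_o)
  expect_true(all(v_o[, , , 4][!cmask] == 0))
  expect_identical(v_o[, , , 1:3][rep(cmask, 3)],
                   v_none[, , , 1:3][rep(cmask, 3)])

  # empty mask in coloc_only_white -> fully empty volume
  st0 <- make_ab_stack(array(c(5L, 0L), c(2, 1, 1)),
                       array(c(0L, 5L), c(2, 1, 1)))
  v0 <- colocalization_volume(st0, coloc_params(1, 2, low_a = 1, low_b = 1,
                                                render_mode = "coloc_only_white"))
  expect_true(all(v0 == 0))
})

test_that("scatter histogram conserves counts and bins the hand example", {
  h <- hand_example()
  hist5 <- scatter_histogram(h$stack, h$params, bins = 5, range = c(0, 4))
  expect_identical(sum(hist5), 4L)  # |S| = 4
  occupied <- which(hist5 > 0, arr.ind = TRUE)
  # intensity pairs (4,0), (2,2), (1,1), (0,4) -> bins (5,1), (3,3), (2,2), (1,5)
  expect_setequal(paste(occupied[, 1], occupied[, 2]),
                  c("5 1", "3 3", "2 2", "1 5"))
  # identical channels: only diagonal bins occupied
  A <- array(sample.int(256, 64, TRUE) - 1L, c(4, 4, 4))
  st <- make_ab_stack(A, A)
  hd <- scatter_histogram(st, coloc_params(1, 2, low_a = 1, low_b = 1), bins = 16)
  expect_true(all(hd[row(hd) != col(hd)] == 0))
  expect_identical(sum(hd), sum(A >= 1))
})

test_that("pseudocolor scatter maps counts through the normalized colormap", {
  h <- matrix(0L, 4, 4); h[2, 3] <- 1L; h[4, 1] <- 10L
  img <- pseudocolor_scatter(h, colormap = "viridis", log_scale = FALSE,
                             background = "black")
  norm <- attr(img, "norm")
  expect_equal(norm[2, 3], 0.1)
  expect_equal(norm[4, 1], 1.0)
  # zero bins are background
  expect_identical(as.vector(img[1, 1, ]), c(0, 0, 0))
  # exactly two non-background pixels
  nonbg <- apply(img, c(1, 2), function(px) any(px != 0))
  expect_identical(sum(nonbg), 2L)
  # all-zero histogram -> uniform background
  img0 <- pseudocolor_scatter(matrix(0L, 3, 3), background = "white")
  expect_true(all(img0 == 1))
  expect_error(pseudocolor_scatter(h, colormap = "not-a-colormap"))
})
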