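test_that("curve_length and linear_distance match elementary geometry", {
  # 3-4-5 segment
  expect_equal(curve_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(linear_distance(rbind(c(0, 0), c(3, 4))), 5)
  # circle of radius 10 sampled at 360 vertices
  th <- seq(0, 2 * pi, length.out = 361)
  circ <- cbind(10 * cos(th), 10 * sin(th))
  expect_equal(curve_length(circ), 2 * pi * 10, tolerance = 1e-3)
  # interior wiggles leave d untouched
  wig <- rbind(c(0, 0), c(2, 3), c(5, -4), c(7, 1), c(10, 0))
  expect_equal(linear_distance(wig), 10)
  # straight segment: lambda equals d
  seg <- rbind(c(1, 1), c(4, 5))
  expect_equal(curve_length(seg), linear_distance(seg))
})

test_that("tortuosity is the arc-to-chord ratio with its invariants", {
  # straight border
  expect_equal(tortuosity(rbind(c(0, 0), c(5, 0), c(10, 0)))$ratio, 1)
  # sawtooth polyline: ratio sqrt(5)
  sp <- phantom_spec("custom", domain_um = c(10, 20),
                     baseline = list(y_um = 5),
                     filopodia = list(n = 5, width_um = 2, height_um = 2,
                                      placement = "even"), noise_sd = 0)
  tr <- generate_border(sp)
  rec <- tortuosity(tr$border)
  expect_equal(rec$ratio, sqrt(5), tolerance = 1e-12)
  expect_equal(rec$lambda_um, 10 * sqrt(5), tolerance = 1e-12)
  # degenerate chord
  expect_error(tortuosity(rbind(c(0, 0), c(1, 1), c(0, 0))), "d = 0")
  # closed polylines have no defined d
  closed <- structure(list(xy = rbind(c(0, 0), c(1, 0), c(0, 0)),
                           open = FALSE), class = "border_polyline")
  expect_error(linear_distance(closed), "closed")
})

test_that("lambda is invariant under rigid motions and vertex refinement", {
  set.seed(42)
  xy <- cbind(cumsum(runif(40, 0.1, 1)), rnorm(40))
  lam <- curve_length(xy)
  for (th in c(0.3, 1.2, 2.7)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy_r <- sweep(xy %*% R, 2, c(5.5, -3.1), `+`)
    expect_equal(curve_length(xy_r), lam, tolerance = 1e-6 * lam)
  }
  # midpoint insertion changes neither lambda nor d
  mid <- (xy[-1, ] + xy[-nrow(xy), ]) / 2
  refined <- matrix(0, nrow(xy) + nrow(mid), 2)
  refined[seq(1, nrow(refined), by = 2), ] <- xy
  refined[seq(2, nrow(refined) - 1, by = 2), ] <- mid
  expect_equal(curve_length(refined), lam, tolerance = 1e-12)
  expect_equal(linear_distance(refined), linear_distance(xy))
  # ratio >= 1 with equality only for collinear vertices
  expect_gt(tortuosity(xy)$ratio, 1)
})

test_that("extract_border traces a straight half-plane split to ratio 1", {
  m <- matrix(FALSE, 40, 60)
  m[1:20, ] <- TRUE
  b <- extract_border(m, pixel_size_um = 0.5)
  rec <- tortuosity(b)
  expect_equal(rec$ratio, 1, tolerance = 1e-3)
  expect_equal(rec$d_um, (60 - 1) * 0.5, tolerance = 1e-6)
  # the line sits midway between rows 20 and 21
  expect_equal(mean(b$xy[, 2]), 20 * 0.5, tolerance = 1e-6)
})

test_that("extract_border recovers phantom geometry from the mask", {
  sp <- phantom_spec("post_branch", noise_sd = 0, seed = 8)
  tr <- generate_border(sp)
  ras <- rasterize_phantom(tr, sp)
  b <- extract_border(ras$mask, sp$pixel_size_um)
  expect_equal(curve_length(b), tr$lambda_um, tolerance = 0.05 * tr$lambda_um)
  expect_equal(linear_distance(b), sp$domain_um[1],
               tolerance = 0.02 * sp$domain_um[1])
})

test_that("extract_border rejects degenerate and disconnected inputs", {
  expect_error(extract_border(matrix(TRUE, 10, 10)), "one phase")
  # a blob that does not span the ROI left-right
  m <- matrix(FALSE, 30, 30)
  m[10:20, 10:20] <- TRUE
  expect_error(extract_border(m, 1), "topology")
  # phi field with no zero crossing
  expect_error(extract_border(matrix(1, 10, 10) + 0.5, 1), "zero level")
})

test_that("ROI clipping restricts the border to the requested window", {
  sp <- phantom_spec("pre_branch", noise_sd = 0, seed = 13)
  tr <- generate_border(sp)
  ras <- rasterize_phantom(tr, sp)
  nr <- nrow(ras$mask)
  nc <- ncol(ras$mask)
  roi <- c(1, nr, 51, 150)  # columns 51..150 only
  b <- extract_border(ras$mask, sp$pixel_size_um, roi = roi)
  expect_gte(min(b$xy[, 1]), (51 - 1) * sp$pixel_size_um - 1e-9)
  expect_lte(max(b$xy[, 1]), 150 * sp$pixel_size_um + 1e-9)
  expect_equal(linear_distance(b), 100 * sp$pixel_size_um, tolerance = 0.5)
})

test_that("group comparison reproduces hand-computed statistics", {
  # pooled-variance t for {1,2,3} vs {4,5,6}
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_value, 0.02131, tolerance = 1e-3)
  expect_equal(cmp$percent_decrease, 100 * (2 - 5) / 2)

  # permutation oracle: the observed |t| is the most extreme of all 20
  # equal-size relabelings, so the exact permutation p is 2/20
  vals <- c(1, 2, 3, 4, 5, 6)
  splits <- combn(6, 3)
  tstats <- apply(splits, 2, function(ix) {
    a <- vals[ix]; b <- vals[-ix]
    sp2 <- (var(a) * 2 + var(b) * 2) / 4
    (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  })
  p_perm <- mean(abs(tstats) >= abs(cmp$t_stat) - 1e-12)
  expect_equal(p_perm, 2 / 20)
  expect_lt(cmp$p_value, 0.05)

  # identical groups
  cmp0 <- compare_groups(c(2, 3, 4), c(2, 3, 4))
  expect_equal(cmp0$t_stat, 0)
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$percent_decrease, 0)

  # degenerate zero-variance groups are handled explicitly
  cmp_const <- compare_groups(rep(11, 10), rep(6, 10))
  expect_equal(cmp_const$percent_decrease, 45.45, tolerance = 1e-3)
  expect_equal(cmp_const$t_stat, Inf)
  expect_equal(cmp_const$p_value, 0)
  cmp_same <- compare_groups(rep(7, 5), rep(7, 5))
  expect_equal(cmp_same$t_stat, 0)
  expect_equal(cmp_same$p_value, 1)

  expect_error(compare_groups(1, c(2, 3)), "at least 2")
})
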