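# independent brute-force polyline length oracle
polyline_len <- function(xy) {
  s <- 0
  for (i in seq_len(nrow(xy) - 1)) {
    s <- s + sqrt((xy[i + 1, 1] - xy[i, 1])^2 + (xy[i + 1, 2] - xy[i, 2])^2)
  }
  unname(s)
}

test_that("border geometry matches closed-form oracles", {
  # straight border, no protrusions
  sp <- phantom_spec("custom", domain_um = c(10, 20),
                     filopodia = list(n = 0), noise_sd = 0)
  tr <- generate_border(sp)
  expect_equal(tr$lambda_um, 10)
  expect_equal(tr$d_um, 10)
  expect_equal(tr$ratio, 1)

  # five even triangular filopodia, base 1 um, height 4 um on a 10 um border
  sp <- phantom_spec("custom", domain_um = c(10, 20),
                     baseline = list(y_um = 5),
                     filopodia = list(n = 5, width_um = 1, height_um = 4,
                                      placement = "even"), noise_sd = 0)
  tr <- generate_border(sp)
  expect_equal(tr$lambda_um, 5 * 2 * sqrt(0.5^2 + 4^2) + 5 * 1,
               tolerance = 1e-12)
  expect_equal(tr$ratio, 4.531, tolerance = 1e-3)

  # sawtooth: five teeth, base 2 um, height 2 um, no flat gaps -> sqrt(5)
  sp <- phantom_spec("custom", domain_um = c(10, 20),
                     baseline = list(y_um = 5),
                     filopodia = list(n = 5, width_um = 2, height_um = 2,
                                      placement = "even"), noise_sd = 0)
  tr <- generate_border(sp)
  expect_equal(tr$ratio, sqrt(5), tolerance = 1e-12)
})

test_that("analytic lambda agrees with a brute-force polyline oracle on random specs", {
  for (seed in 1:6) {
    sp <- phantom_spec(if (seed %% 2) "pre_branch" else "post_branch",
                       seed = seed)
    tr <- generate_border(sp)
    expect_equal(tr$lambda_um, polyline_len(tr$border),
                 tolerance = 1e-9)
    expect_gte(tr$ratio, 1)
    # open polyline spanning the full domain width
    expect_equal(unname(tr$border[1, 1]), 0)
    expect_equal(unname(tr$border[nrow(tr$border), 1]), sp$domain_um[1])
  }
})

test_that("identical (spec, seed) pairs reproduce bit-identical phantoms", {
  sp <- phantom_spec("pre_branch", noise_sd = 0.1, seed = 99)
  t1 <- generate_border(sp)
  t2 <- generate_border(sp)
  expect_identical(t1$border, t2$border)
  r1 <- rasterize_phantom(t1)
  r2 <- rasterize_phantom(t2)
  expect_identical(r1$image, r2$image)
  # a different seed changes the geometry
  t3 <- generate_border(phantom_spec("pre_branch", noise_sd = 0.1,
                                     seed = 100))
  expect_false(isTRUE(all.equal(t1$ratio, t3$ratio)))
})

test_that("infeasible protrusion density raises an error naming the maximum", {
  sp <- phantom_spec("custom", domain_um = c(10, 20),
                     filopodia = list(n = 20, width_um = 1), noise_sd = 0)
  expect_error(generate_border(sp), "max feasible density")
})

test_that("spec validation enforces the geometric invariants", {
  expect_error(phantom_spec(intensity_epithelium = 0.5,
                            intensity_mesenchyme = 0.5), "differ")
  expect_error(phantom_spec(pixel_size_um = -0.1), "positive")
  expect_error(phantom_spec(filopodia = list(length_range = c(9, 2))),
               "min")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("lambda increases with filopodia density and length (d fixed)", {
  lam_d <- vapply(c(4, 8, 12, 16), function(n) {
    sp <- phantom_spec("custom", domain_um = c(20, 40),
                       filopodia = list(n = n, width_um = 1,
                                        placement = "even", height_um = 5),
                       noise_sd = 0)
    generate_border(sp)$lambda_um
  }, numeric(1))
  expect_true(all(diff(lam_d) > 0))
  lam_h <- vapply(c(2, 4, 6, 8, 10), function(h) {
    sp <- phantom_spec("custom", domain_um = c(20, 40),
                       filopodia = list(n = 8, width_um = 1,
                                        placement = "even", height_um = h),
                       noise_sd = 0)
    generate_border(sp)$lambda_um
  }, numeric(1))
  expect_true(all(diff(lam_h) > 0))
})

test_that("rasterization honors phases, area, bias and seeding", {
  sp <- phantom_spec("custom", domain_um = c(10, 20), pixel_size_um = 0.2,
                     filopodia = list(n = 3, width_um = 1.2,
                                      height_um = 5, placement = "even"),
                     baseline = list(y_um = 8), noise_sd = 0)
  tr <- generate_border(sp)
  ras <- rasterize_phantom(tr, sp)
  # noise-free image carries exactly the two phase intensities
  expect_setequal(unique(as.vector(ras$image)), c(0.3, 0.7))
  # mask area fraction vs the shoelace area of the epithelium polygon
  poly <- rbind(c(0, 0), tr$border, c(10, 0))
  shoelace <- abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                        c(poly[-1, 1], poly[1, 1]) * poly[, 2])) / 2
  area_frac_true <- shoelace / (10 * 20)
  expect_equal(mean(ras$mask), area_frac_true, tolerance = 0.01)

  # seeded noise is bit-reproducible
  spn <- phantom_spec("pre_branch", noise_sd = 0.1, seed = 4)
  trn <- generate_border(spn)
  expect_identical(rasterize_phantom(trn)$image, rasterize_phantom(trn)$image)

  # linear bias makes per-column means monotone
  spb <- phantom_spec("custom", domain_um = c(10, 20),
                      filopodia = list(n = 0), noise_sd = 0,
                      bias = list(type = "linear", amplitude = 0.3))
  trb <- generate_border(spb)
  rb <- rasterize_phantom(trb, spb)
  col_means <- colMeans(rb$image)
  expect_true(all(diff(col_means) > 0))

  # sub-3-pixel protrusions trigger the resolution warning
  spw <- phantom_spec("custom", pixel_size_um = 0.5,
                      filopodia = list(n = 3, width_um = 1,
                                       height_um = 5, placement = "even"),
                      noise_sd = 0)
  expect_warning(rasterize_phantom(generate_border(spw), spw), "3 pixels")
})

test_that("mask-derived border length converges to analytic lambda under grid refinement", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(px) {
    sps <- lapply(c(31, 32), function(s)
      phantom_spec("pre_branch", pixel_size_um = px, noise_sd = 0, seed = s))
    mean(vapply(sps, function(sp) {
      tr <- generate_border(sp)
      ras <- suppressWarnings(rasterize_phantom(tr, sp))
      b <- extract_border(ras$mask, px)
      abs(curve_length(b) - tr$lambda_um) / tr$lambda_um
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("make_dataset builds a reproducible two-group collection", {
  ov <- list(domain_um = c(16, 24),
             baseline = list(y_um = 10),
             post = list(baseline = list(y_um = 4),
                         lobes = list(n = 2, width_um = 6,
                                      depth_range = c(12, 18))))
  ds <- make_dataset(n_pre = 3, n_post = 3, seed = 7, overrides = ov)
  expect_equal(nrow(ds$table), 6)
  expect_equal(sum(ds$table$group == "pre"), 3)
  expect_true(min(ds$table$ratio[ds$table$group == "pre"]) >
                max(ds$table$ratio[ds$table$group == "post"]))
  ds2 <- make_dataset(n_pre = 3, n_post = 3, seed = 7, overrides = ov)
  expect_identical(ds$table, ds2$table)
  expect_error(make_dataset(n_pre = 0, n_post = 3), ">= 1")
})

test_that("dataset files round-trip through the standard formats", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(n_pre = 1, n_post = 1, seed = 3,
                     overrides = list(domain_um = c(12, 18),
                                      baseline = list(y_um = 8),
                                      post = list(
                                        baseline = list(y_um = 3),
                                        lobes = list(n = 1, width_um = 6,
                                                     depth_range = c(8, 12)))),
                     dir = dir)
  expect_true(file.exists(file.path(dir, "pre_01.tif")))
  expect_true(file.exists(file.path(dir, "post_01_mask.png")))
  img <- read_image(file.path(dir, "pre_01.tif"))
  expect_equal(dim(img), dim(ds$phantoms[[1]]$image))
  expect_equal(img, ds$phantoms[[1]]$image, tolerance = 2e-5)  # 16-bit
  m <- read_mask_png(file.path(dir, "post_01_mask.png"))
  expect_identical(m, ds$phantoms[[2]]$mask)
  tab <- read.csv(file.path(dir, "ground_truth.csv"),
                  stringsAsFactors = FALSE)
  expect_equal(tab$ratio, ds$table$ratio, tolerance = 1e-12)
  # level-set fields round-trip through float TIFF with a rescale sidecar
  phi <- matrix(rnorm(30, 0, 5), 5, 6)
  pth <- file.path(dir, "phi.tif")
  write_phi_tiff(phi, pth)
  expect_true(file.exists(paste0(pth, ".json")))
  expect_equal(read_phi_tiff(pth), phi, tolerance = 1e-6)
})
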