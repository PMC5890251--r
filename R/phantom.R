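# run code under a temporary RNG state, restoring the caller's state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic tissue phantom
#'
#' Describes a two-phase tissue image whose epithelial-mesenchymal border has
#' analytically known geometry. The coordinate convention is image-style:
#' origin at the top-left, x rightward, y downward, the center of pixel
#' (row i, col j) at ((j - 0.5) * pixel, (i - 0.5) * pixel) micrometers. The
#' epithelium occupies the region above the border (smaller y) and its
#' protrusions extend downward into the mesenchyme.
#'
#' Group defaults emulate the two follicle stages: `"pre_branch"` borders are
#' fringed with thin filopodia (per-phantom linear density drawn from
#' `filopodia$density_range`, lengths from `filopodia$length_range`, default
#' 2-10 um), `"post_branch"` borders carry a few deep smooth lobes (branch
#' cross-sections). `"custom"` applies exactly what is passed.
#'
#' @param group `"pre_branch"`, `"post_branch"` or `"custom"`.
#' @param domain_um numeric length 2, domain width and height in micrometers.
#' @param pixel_size_um raster calibration, micrometers per pixel.
#' @param baseline list: `type` (`"flat"` or `"sine"`), `y_um` (border depth
#'   from the top; group-dependent default), `amplitude_um`, `period_um`.
#' @param filopodia list: `density_range` (protrusions per micrometer of
#'   border; a length-2 range sampled once per phantom, or a single number),
#'   `length_range` (um), `width_um` (base width), `shape` (`"triangular"`,
#'   `"rounded"` or `"scallop"`), `placement` (`"random"` hard-rod or
#'   `"even"`), optional fixed `n` and `height_um` overriding the draws.
#' @param lobes list (post-branch): `n`, `depth_range` (um), `width_um`.
#' @param intensity_epithelium,intensity_mesenchyme phase intensities in
#'   `[0, 1]`; must differ.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param bias list: `type` (`"none"`, `"linear"`, `"quadratic"`) and
#'   `amplitude` of the smooth intensity-inhomogeneity field.
#' @param seed integer; identical (spec, seed) pairs reproduce bit-identical
#'   phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(group = c("pre_branch", "post_branch", "custom"),
                         domain_um = c(40, 60),
                         pixel_size_um = 0.2,
                         baseline = list(),
                         filopodia = list(),
                         lobes = list(),
                         intensity_epithelium = 0.7,
                         intensity_mesenchyme = 0.3,
                         noise_sd = 0.05,
                         bias = list(type = "none", amplitude = 0),
                         seed = 1L) {
  group <- match.arg(group)
  base_def <- list(type = "flat",
                   y_um = switch(group, pre_branch = 24, post_branch = 12, 24),
                   amplitude_um = 0, period_um = 20)
  filo_def <- list(density_range = c(0.6, 1.0), length_range = c(2, 10),
                   width_um = 1.0, shape = "triangular", placement = "random",
                   n = NULL, height_um = NULL)
  lobe_def <- list(n = 3, depth_range = c(22, 38), width_um = 10)
  spec <- structure(list(
    group = group,
    domain_um = as.numeric(domain_um),
    pixel_size_um = pixel_size_um,
    baseline = utils::modifyList(base_def, baseline),
    filopodia = utils::modifyList(filo_def, filopodia,
                                  keep.null = FALSE),
    lobes = utils::modifyList(lobe_def, lobes),
    intensity_epithelium = intensity_epithelium,
    intensity_mesenchyme = intensity_mesenchyme,
    noise_sd = noise_sd,
    bias = utils::modifyList(list(type = "none", amplitude = 0), bias),
    seed = as.integer(seed)
  ), class = "phantom_spec")
  # accept scalar density
  dr <- spec$filopodia$density_range
  if (length(dr) == 1) spec$filopodia$density_range <- c(dr, dr)
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  errs <- character()
  chk_pos <- function(v, nm) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      errs <<- c(errs, sprintf("`%s` must be strictly positive", nm))
    }
  }
  chk_pos(spec$domain_um, "domain_um")
  chk_pos(spec$pixel_size_um, "pixel_size_um")
  chk_pos(spec$filopodia$width_um, "filopodia$width_um")
  lr <- spec$filopodia$length_range
  chk_pos(lr, "filopodia$length_range")
  if (is.numeric(lr) && length(lr) == 2 && lr[1] > lr[2]) {
    errs <- c(errs, "filopodia length min must be <= max")
  }
  if (any(spec$filopodia$density_range < 0)) {
    errs <- c(errs, "filopodia density must be >= 0")
  }
  chk_pos(spec$lobes$width_um, "lobes$width_um")
  chk_pos(spec$lobes$depth_range, "lobes$depth_range")
  if (spec$intensity_epithelium == spec$intensity_mesenchyme) {
    errs <- c(errs, "phase intensities must differ")
  }
  ints <- c(spec$intensity_epithelium, spec$intensity_mesenchyme)
  if (any(ints < 0 | ints > 1)) {
    errs <- c(errs, "phase intensities must lie in [0, 1]")
  }
  if (spec$noise_sd < 0) errs <- c(errs, "`noise_sd` must be >= 0")
  if (!spec$bias$type %in% c("none", "linear", "quadratic")) {
    errs <- c(errs, "bias type must be none, linear or quadratic")
  }
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  invisible(spec)
}

# baseline curve y(x)
baseline_y <- function(spec, x) {
  b <- spec$baseline
  if (b$type == "sine" && b$amplitude_um > 0) {
    b$y_um + b$amplitude_um * sin(2 * pi * x / b$period_um)
  } else {
    rep(b$y_um, length(x))
  }
}

# sample protrusion base centers: uniform hard-rod model (exact, no rejection)
sample_centers <- function(n, width, w, placement) {
  max_n <- floor(width / w)
  if (n > max_n) {
    stop(sprintf(paste0("infeasible protrusion density: %d bases of width ",
                        "%.3g um cannot fit in %.3g um without overlap ",
                        "(max feasible density %.3g per um)"),
                 n, w, width, max_n / width), call. = FALSE)
  }
  if (n == 0) return(numeric(0))
  if (placement == "even") {
    if (width / n < w - 1e-9) {
      stop("even placement infeasible: spacing below base width",
           call. = FALSE)
    }
    (seq_len(n) - 0.5) * width / n
  } else {
    free <- width - n * w
    sort(stats::runif(n, 0, free)) + (seq_len(n) - 1) * w + w / 2
  }
}

# vertices of one protrusion (downward into the mesenchyme), excluding its
# baseline endpoints; also returns the graph profile on a fine grid
feature_vertices <- function(center, w, h, shape, y0, arc_step = 0.02) {
  half <- w / 2
  if (shape == "triangular") {
    cbind(x = center, y = y0 + h)
  } else if (shape == "rounded") {
    xs <- seq(center - half, center + half, by = min(arc_step, w / 16))
    xs <- xs[xs > center - half & xs < center + half]
    cbind(x = xs, y = y0 + h / 2 * (1 + cos(2 * pi * (xs - center) / w)))
  } else if (shape == "scallop") {
    th <- seq(pi, 0, length.out = max(32, ceiling(pi * half / arc_step)))
    cbind(x = center + half * cos(th), y = y0 + half * sin(th))[-c(1), ,
                                                               drop = FALSE]
  } else if (shape == "lobe") {
    # vertical walls joined by a semicircular tip of radius w/2 at depth h
    r <- half
    wall <- h - r
    th <- seq(pi, 0, length.out = max(64, ceiling(pi * r / arc_step)))
    arc <- cbind(x = center + r * cos(th), y = y0 + wall + r * sin(th))
    rbind(cbind(x = center - r, y = y0 + wall), arc,
          cbind(x = center + r, y = y0 + wall))
  } else {
    stop("unknown protrusion shape: ", shape, call. = FALSE)
  }
}

# graph profile y(x) of one protrusion relative to baseline depth y0
feature_profile <- function(x, center, w, h, shape, y0) {
  half <- w / 2
  u <- x - center
  inside <- abs(u) < half
  y <- rep(0, length(x))
  if (shape == "triangular") {
    y[inside] <- h * (1 - abs(u[inside]) / half)
  } else if (shape == "rounded") {
    y[inside] <- h / 2 * (1 + cos(pi * u[inside] / half))
  } else if (shape == "scallop") {
    y[inside] <- sqrt(pmax(half^2 - u[inside]^2, 0))
  } else if (shape == "lobe") {
    y[inside] <- (h - half) + sqrt(pmax(half^2 - u[inside]^2, 0))
  }
  y
}

#' Generate the ground-truth border of a phantom
#'
#' Draws the border geometry prescribed by a [phantom_spec()] (seeded, hence
#' reproducible) and returns it as an open polyline spanning the full domain
#' width together with its exact polygonal arc length `lambda_um`, chord
#' `d_um` and tortuosity `ratio = lambda / d`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `ground_truth`: list with `border` (two-column
#'   matrix of vertices in micrometers), `lambda_um`, `d_um`, `ratio`,
#'   `features` (data frame of realized protrusions), `profile_fn`
#'   (vectorized exact border-depth function used by the rasterizer) and
#'   `spec`.
#' @export
generate_border <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  W <- spec$domain_um[1]
  H <- spec$domain_um[2]
  feat <- with_seed(spec$seed, {
    if (spec$group == "post_branch") {
      lb <- spec$lobes
      data.frame(center = sample_centers(lb$n, W, lb$width_um, "even"),
                 width = lb$width_um,
                 height = stats::runif(lb$n, lb$depth_range[1],
                                       lb$depth_range[2]),
                 shape = "lobe", stringsAsFactors = FALSE)
    } else {
      fp <- spec$filopodia
      n <- fp$n
      if (is.null(n)) {
        density <- stats::runif(1, fp$density_range[1], fp$density_range[2])
        n <- round(density * W)
      }
      if (n == 0) {
        data.frame(center = numeric(0), width = numeric(0),
                   height = numeric(0), shape = character(0),
                   stringsAsFactors = FALSE)
      } else {
        centers <- sample_centers(n, W, fp$width_um, fp$placement)
        heights <- if (!is.null(fp$height_um)) rep(fp$height_um, n)
        else stats::runif(n, fp$length_range[1], fp$length_range[2])
        data.frame(center = centers, width = fp$width_um, height = heights,
                   shape = fp$shape, stringsAsFactors = FALSE)
      }
    }
  })
  ymax_base <- spec$baseline$y_um + abs(spec$baseline$amplitude_um)
  if (nrow(feat) && any(feat$height + ymax_base > H)) {
    stop("protrusions extend below the domain; increase domain height",
         call. = FALSE)
  }

  sine <- spec$baseline$type == "sine" && spec$baseline$amplitude_um > 0
  base_seg <- function(x0, x1) {
    if (x1 <= x0 + 1e-12) return(NULL)
    xs <- if (sine) seq(x0, x1, by = 0.05) else c(x0, x1)
    if (xs[length(xs)] < x1) xs <- c(xs, x1)
    cbind(x = xs, y = baseline_y(spec, xs))
  }
  pieces <- list(cbind(x = 0, y = baseline_y(spec, 0)))
  xprev <- 0
  if (nrow(feat)) {
    for (i in seq_len(nrow(feat))) {
      x0 <- feat$center[i] - feat$width[i] / 2
      x1 <- feat$center[i] + feat$width[i] / 2
      y0 <- baseline_y(spec, feat$center[i])
      pieces <- c(pieces, list(base_seg(xprev, x0)),
                  list(cbind(x = x0, y = y0)),
                  list(feature_vertices(feat$center[i], feat$width[i],
                                        feat$height[i], feat$shape[i], y0)),
                  list(cbind(x = x1, y = y0)))
      xprev <- x1
    }
  }
  pieces <- c(pieces, list(base_seg(xprev, W)),
              list(cbind(x = W, y = baseline_y(spec, W))))
  border <- do.call(rbind, Filter(Negate(is.null), pieces))
  # strip stray element names inherited from the named cbind() pieces
  border <- matrix(as.numeric(border), ncol = 2,
                   dimnames = list(NULL, c("x_um", "y_um")))
  # drop consecutive duplicate vertices
  keep <- c(TRUE, rowSums(abs(diff(border))) > 1e-12)
  border <- border[keep, , drop = FALSE]

  lambda <- sum(sqrt(rowSums(diff(border)^2)))
  d <- sqrt(sum((border[nrow(border), ] - border[1, ])^2))

  profile_fn <- function(x) {
    y <- baseline_y(spec, x)
    if (nrow(feat)) {
      for (i in seq_len(nrow(feat))) {
        y <- y + feature_profile(x, feat$center[i], feat$width[i],
                                 feat$height[i], feat$shape[i], 0)
      }
    }
    y
  }

  structure(list(border = border, lambda_um = lambda, d_um = d,
                 ratio = lambda / d, features = feat,
                 profile_fn = profile_fn, spec = spec),
            class = "ground_truth")
}

#' Rasterize a phantom
#'
#' Renders the two-phase image of a ground-truth border: each pixel takes the
#' intensity of the phase containing its center, plus the optional smooth bias
#' field, plus seeded additive Gaussian noise, clipped to `[0, 1]`. The
#' returned mask is the noise-free phase assignment (`TRUE` = epithelium).
#'
#' @param truth a [generate_border()] result.
#' @param spec the matching [phantom_spec()]; defaults to `truth$spec`.
#' @return list with `image` and `mask` matrices (rows = y, cols = x).
#' @export
rasterize_phantom <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "ground_truth"))
  px <- spec$pixel_size_um
  W <- spec$domain_um[1]
  H <- spec$domain_um[2]
  if (nrow(truth$features) && any(truth$features$width / px < 3)) {
    warning("narrowest protrusion spans fewer than 3 pixels; ",
            "consider a smaller pixel_size_um", call. = FALSE)
  }
  nc <- round(W / px)
  nr <- round(H / px)
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px
  prof <- truth$profile_fn(xc)
  mask <- outer(yc, prof, `<`)
  img <- ifelse(mask, spec$intensity_epithelium, spec$intensity_mesenchyme)
  if (spec$bias$type == "linear") {
    img <- img + matrix(spec$bias$amplitude * (xc / W - 0.5),
                        nr, nc, byrow = TRUE)
  } else if (spec$bias$type == "quadratic") {
    # smooth low-order polynomial ridge along the image midline:
    # zero at the top and bottom edges, maximal at mid-height
    t <- yc / H
    img <- img + matrix(spec$bias$amplitude * 4 * t * (1 - t), nr, nc)
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed + 1L,
                     img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd),
                                  nr, nc))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate a two-group phantom dataset
#'
#' Builds `n_pre` pre-branch and `n_post` post-branch phantoms with
#' per-phantom seeds derived deterministically from the master seed, and
#' returns (optionally writes) the images, masks and the analytic
#' ground-truth table.
#'
#' @param n_pre,n_post number of phantoms per group (>= 1).
#' @param overrides named list of [phantom_spec()] arguments applied to every
#'   phantom (group-specific lists under `pre` / `post` are also accepted).
#' @param seed master seed.
#' @param dir optional output directory; images are written as 16-bit TIFF,
#'   masks as PNG, the ground-truth table as CSV and the specs as JSON.
#' @return list with `table` (data frame: id, group, lambda_um, d_um, ratio,
#'   seed) and `phantoms` (list of per-phantom `spec`, `truth`, `image`,
#'   `mask`).
#' @export
make_dataset <- function(n_pre = 10, n_post = 10, overrides = list(),
                         seed = 1L, dir = NULL) {
  if (n_pre < 1 || n_post < 1) {
    stop("`n_pre` and `n_post` must both be >= 1", call. = FALSE)
  }
  n <- n_pre + n_post
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  groups <- rep(c("pre_branch", "post_branch"), c(n_pre, n_post))
  ids <- c(sprintf("pre_%02d", seq_len(n_pre)),
           sprintf("post_%02d", seq_len(n_post)))
  common <- overrides[setdiff(names(overrides), c("pre", "post"))]
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- groups[i]
    args <- utils::modifyList(
      c(list(group = grp, seed = seeds[i]), common),
      if (grp == "pre_branch") overrides$pre %||% list()
      else overrides$post %||% list())
    sp <- do.call(phantom_spec, args)
    truth <- generate_border(sp)
    ras <- rasterize_phantom(truth, sp)
    phantoms[[i]] <- list(id = ids[i], spec = sp, truth = truth,
                          image = ras$image, mask = ras$mask)
    rows[[i]] <- data.frame(id = ids[i],
                            group = sub("_branch", "", grp),
                            lambda_um = truth$lambda_um,
                            d_um = truth$d_um,
                            ratio = truth$ratio,
                            seed = seeds[i],
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(dir)) {
    write_dataset(phantoms, tab, dir)
  }
  list(table = tab, phantoms = phantoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phantom with an exactly prescribed tortuosity
#'
#' Builds a deterministic calibration phantom whose analytic lambda/d equals
#' `target_ratio` exactly: `n` identical capsule-shaped protrusions (vertical
#' walls joined by a semicircular tip) of width `width_um`, evenly spaced
#' along a flat border, with the depth solved in closed form from the
#' target. Used to probe how accurately the measurement pipeline recovers a
#' known tortuosity. The capsule shape is chosen deliberately: its smallest
#' boundary feature is the tip radius `width_um / 2` (7.5 px at the default
#' calibration), so the recovery error reflects the pipeline rather than the
#' subpixel sampling limit that sharp triangular tips or touching-teeth
#' valleys would impose.
#'
#' @param target_ratio desired lambda/d (>= 1).
#' @param n number of protrusions.
#' @param width_um protrusion width (um).
#' @param domain_um domain size (um); the border spans the full width.
#' @param ... further [phantom_spec()] arguments (e.g. `pixel_size_um`,
#'   `noise_sd`, `seed`).
#' @return a [phantom_spec()] whose [generate_border()] ratio equals
#'   `target_ratio` to rounding accuracy.
#' @export
ratio_phantom_spec <- function(target_ratio, n = 8, width_um = 3,
                               domain_um = c(40, 48), ...) {
  stopifnot(target_ratio >= 1)
  if (target_ratio == 1) {
    return(phantom_spec("custom", domain_um = domain_um,
                        baseline = list(y_um = 4),
                        filopodia = list(n = 0), ...))
  }
  # capsule adds 2*(D - w/2) + pi*w/2 - w of border length per protrusion
  added <- (target_ratio - 1) * domain_um[1] / n
  depth <- (added + width_um - pi * width_um / 2) / 2 + width_um / 2
  if (depth <= width_um / 2) {
    stop("target_ratio too small for the capsule geometry; ",
         "reduce `n` or `width_um`", call. = FALSE)
  }
  phantom_spec("custom", domain_um = domain_um,
               baseline = list(y_um = 4),
               filopodia = list(n = n, width_um = width_um,
                                height_um = depth, shape = "lobe",
                                placement = "even"),
               ...)
}

write_dataset <- function(phantoms, tab, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  for (p in phantoms) {
    write_image_tiff(p$image, file.path(dir, paste0(p$id, ".tif")))
    write_mask_png(p$mask, file.path(dir, paste0(p$id, "_mask.png")))
  }
  utils::write.csv(tab, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  specs <- lapply(phantoms, function(p) p$spec[setdiff(names(p$spec),
                                                       "profile_fn")])
  names(specs) <- vapply(phantoms, `[[`, "", "id")
  jsonlite::write_json(specs, file.path(dir, "specs.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
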