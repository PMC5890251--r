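#' Validate and normalize a run configuration
#'
#' Fills documented defaults and aggregates every configuration error into a
#' single message. A configuration is a plain named list; unknown fields are
#' rejected.
#'
#' Fields: `mode` (`"simulate"`, `"segment"`, `"measure"`, `"compare"`,
#' `"full"`), `n_pre`, `n_post`, `phantom` (overrides for [phantom_spec()]),
#' `acm` (arguments for [acm_params()]), `roi`, `sides`, `polarity`,
#' `pixel_size_um`, `input` (paths, for non-simulate modes), `groups`
#' (for `mode = "compare"`: list of two numeric vectors), `out_dir`, `seed`.
#'
#' @param config named list (possibly empty).
#' @return normalized configuration list with class `run_config`.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(mode = "full", n_pre = 10, n_post = 10,
                   phantom = list(), acm = list(), roi = NULL,
                   sides = c("left", "right"), polarity = "bright",
                   pixel_size_um = NULL, input = NULL, groups = NULL,
                   out_dir = NULL, seed = 1L)
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config field(s): ",
                           paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))],
                           keep.null = TRUE)
  if (!cfg$mode %in% c("simulate", "segment", "measure", "compare", "full")) {
    errs <- c(errs, sprintf("invalid mode: '%s'", cfg$mode))
  }
  if (cfg$mode %in% c("simulate", "full")) {
    if (!is.numeric(cfg$n_pre) || cfg$n_pre < 1 ||
        !is.numeric(cfg$n_post) || cfg$n_post < 1) {
      errs <- c(errs, "`n_pre` and `n_post` must be >= 1")
    }
  }
  params <- tryCatch(do.call(acm_params, cfg$acm),
                     error = function(e) {
                       errs <<- c(errs, paste0("acm: ", conditionMessage(e)))
                       NULL
                     })
  if (cfg$mode %in% c("segment", "measure")) {
    if (is.null(cfg$input)) {
      errs <- c(errs, sprintf("mode '%s' requires `input` paths", cfg$mode))
    } else {
      missing <- cfg$input[!file.exists(cfg$input)]
      if (length(missing)) {
        errs <- c(errs, paste0("input path(s) not found: ",
                               paste(missing, collapse = ", ")))
      }
    }
    if (is.null(cfg$pixel_size_um)) {
      errs <- c(errs, sprintf("mode '%s' requires `pixel_size_um`", cfg$mode))
    }
  }
  if (cfg$mode == "compare") {
    if (is.null(cfg$groups) || length(cfg$groups) != 2) {
      errs <- c(errs, "mode 'compare' requires `groups`, a list of exactly two ratio vectors")
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    errs <- c(errs, "`seed` must be a single integer")
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$acm_params <- params
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from JSON
#' @param path JSON file whose fields mirror [validate_config()].
#' @return normalized `run_config`.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

# segment one image and measure its border tortuosity
measure_image <- function(image, params, pixel_size_um, roi, sides, polarity,
                          id = NULL, group = NA_character_) {
  seg <- acm_segment(image, params, polarity = polarity)
  border <- extract_border(seg$phi, pixel_size_um, roi = roi, sides = sides,
                           id = id)
  list(record = tortuosity(border, id = id, group = group),
       border = border, segmentation = seg)
}

#' Run the end-to-end tortuosity pipeline
#'
#' Orchestrates simulate -> segment -> measure -> compare. In the default
#' simulate-based modes it generates the two-group phantom dataset, segments
#' every image with the hybrid active-contour model, extracts each border,
#' computes the lambda/d records side by side with their analytic ground
#' truth, and compares the groups. Per-image failures are caught, logged and
#' excluded (with a count in the manifest); the run fails only if every image
#' fails.
#'
#' @param config a [validate_config()] list (or raw named list).
#' @return list with `manifest` (config snapshot, per-image status, output
#'   index, package version, timestamp), and mode-dependent elements:
#'   `dataset`, `records` (measured vs analytic ratios), `comparison`.
#' @export
run_full <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config
  else validate_config(config)
  outputs <- character()
  manifest <- list(config = cfg[setdiff(names(cfg), "acm_params")],
                   version = as.character(utils::packageVersion("emtort")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))

  if (cfg$mode == "compare") {
    cmp <- compare_groups(cfg$groups[[1]], cfg$groups[[2]])
    if (!is.null(cfg$out_dir)) {
      outputs <- c(outputs, write_comparison(cmp, cfg$out_dir))
    }
    manifest$outputs <- outputs
    return(list(manifest = manifest, comparison = cmp))
  }

  if (cfg$mode %in% c("measure", "segment")) {
    results <- lapply(cfg$input, function(path) {
      tryCatch({
        if (cfg$mode == "measure") {
          mask <- read_mask_png(path)
          border <- extract_border(mask, cfg$pixel_size_um, roi = cfg$roi,
                                   sides = cfg$sides, id = basename(path))
          list(record = tortuosity(border, id = basename(path)))
        } else {
          img <- read_image(path)
          measure_image(img, cfg$acm_params, cfg$pixel_size_um, cfg$roi,
                        cfg$sides, cfg$polarity, id = basename(path))
        }
      }, error = function(e) {
        message(basename(path), " failed: ", conditionMessage(e))
        list(record = NULL, error = conditionMessage(e))
      })
    })
    recs <- lapply(results, `[[`, "record")
    failed <- vapply(recs, is.null, TRUE)
    if (all(failed)) stop("all inputs failed", call. = FALSE)
    records <- do.call(rbind, recs[!failed])
    manifest$image_status <- stats::setNames(
      ifelse(failed, "failed", "ok"), basename(cfg$input))
    manifest$n_failed <- sum(failed)
    if (!is.null(cfg$out_dir)) {
      outputs <- c(outputs, write_records(records, cfg$out_dir))
    }
    manifest$outputs <- outputs
    return(list(manifest = manifest, records = records,
                results = if (cfg$mode == "segment") results else NULL))
  }

  # simulate or full
  ds <- make_dataset(cfg$n_pre, cfg$n_post, overrides = cfg$phantom,
                     seed = cfg$seed,
                     dir = if (!is.null(cfg$out_dir))
                       file.path(cfg$out_dir, "phantoms") else NULL)
  manifest$seed <- cfg$seed
  if (cfg$mode == "simulate") {
    manifest$outputs <- outputs
    return(list(manifest = manifest, dataset = ds))
  }

  status <- character(length(ds$phantoms))
  rows <- vector("list", length(ds$phantoms))
  for (i in seq_along(ds$phantoms)) {
    ph <- ds$phantoms[[i]]
    res <- tryCatch({
      m <- measure_image(ph$image, cfg$acm_params, ph$spec$pixel_size_um,
                         cfg$roi, cfg$sides, cfg$polarity, id = ph$id,
                         group = ds$table$group[i])
      rec <- m$record
      rec$analytic_lambda_um <- ph$truth$lambda_um
      rec$analytic_ratio <- ph$truth$ratio
      rec$rel_error <- abs(rec$ratio - ph$truth$ratio) / ph$truth$ratio
      rows[[i]] <- rec
      "ok"
    }, error = function(e) paste0("failed: ", conditionMessage(e)))
    status[i] <- res
    if (res != "ok") message(ph$id, " ", res)
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(records) || nrow(records) == 0) {
    stop("all images failed segmentation/measurement", call. = FALSE)
  }
  n_failed <- sum(status != "ok")
  comparison <- compare_groups(records$ratio[records$group == "pre"],
                               records$ratio[records$group == "post"])
  manifest$image_status <- stats::setNames(status,
                                           vapply(ds$phantoms, `[[`, "",
                                                  "id"))
  manifest$n_failed <- n_failed
  if (!is.null(cfg$out_dir)) {
    outputs <- c(outputs,
                 write_records(records, cfg$out_dir),
                 write_comparison(comparison, cfg$out_dir))
    man_path <- file.path(cfg$out_dir, "manifest.json")
    manifest$outputs <- c(outputs, man_path)
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
    outputs <- manifest$outputs
  }
  manifest$outputs <- outputs
  list(manifest = manifest, dataset = ds, records = records,
       comparison = comparison)
}

write_records <- function(records, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  path <- file.path(dir, "tortuosity_records.csv")
  utils::write.csv(records, path, row.names = FALSE)
  path
}

write_comparison <- function(cmp, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  path <- file.path(dir, "comparison.json")
  jsonlite::write_json(unclass(cmp), path, auto_unbox = TRUE, digits = NA)
  path
}
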