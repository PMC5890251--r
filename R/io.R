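#' Read a grayscale image
#'
#' Reads a TIFF or PNG image as a numeric matrix. Multi-channel images are
#' reduced to their first channel; values outside `[0, 1]` are rescaled (with
#' a message).
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = ,
                tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1) {
    message(sprintf("rescaling intensities from [%.3g, %.3g] to [0, 1]",
                    rng[1], rng[2]))
    img <- (img - rng[1]) / diff(rng)
  }
  img
}

#' Write a matrix as 16-bit grayscale TIFF
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_image_tiff <- function(image, path) {
  ok <- try(tiff::writeTIFF(pmin(pmax(image, 0), 1), path,
                            bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write TIFF: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write a binary mask as PNG (0/255)
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  ok <- try(png::writePNG((mask > 0) * 1.0, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write PNG: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path file path.
#' @return logical matrix (`TRUE` where the pixel is set).
#' @export
read_mask_png <- function(path) {
  read_image(path) > 0.5
}

#' Write a level-set field as 32-bit float TIFF
#'
#' TIFF storage is defined on `[0, 1]`, so the field is affinely rescaled
#' and the offset/scale are stored in a JSON sidecar (`<path>.json`);
#' [read_phi_tiff()] undoes the transform.
#'
#' @param phi numeric matrix (level-set values, any range).
#' @param path output path.
#' @export
write_phi_tiff <- function(phi, path) {
  lo <- min(phi)
  span <- max(phi) - lo
  if (span == 0) span <- 1
  ok <- try(tiff::writeTIFF((phi - lo) / span, path,
                            bits.per.sample = 32L, reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write TIFF: ", path, call. = FALSE)
  }
  jsonlite::write_json(list(offset = lo, scale = span),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a level-set field written by [write_phi_tiff()]
#' @param path TIFF path (the `.json` sidecar must sit next to it).
#' @return numeric matrix.
#' @export
read_phi_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  tiff::readTIFF(path) * meta$scale + meta$offset
}

#' Write a border polyline as CSV
#' @param border a [extract_border()] result (or two-column matrix).
#' @param path output path.
#' @param id identifier stored in the `id` column.
#' @export
write_border_csv <- function(border, path, id = NULL) {
  xy <- if (inherits(border, "border_polyline")) border$xy else border
  id <- id %||% (if (inherits(border, "border_polyline")) border$id else NA)
  utils::write.csv(data.frame(id = id,
                              vertex_index = seq_len(nrow(xy)),
                              x_um = xy[, 1], y_um = xy[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
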