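# Liang-Barsky clipping of one segment to a rectangle c(x0, x1, y0, y1);
# returns NULL or a 2x2 matrix of clipped endpoints
clip_segment <- function(p, q, r) {
  d <- q - p
  t0 <- 0
  t1 <- 1
  for (k in 1:2) {
    lo <- r[2 * k - 1]
    hi <- r[2 * k]
    if (d[k] == 0) {
      if (p[k] < lo || p[k] > hi) return(NULL)
    } else {
      ta <- (lo - p[k]) / d[k]
      tb <- (hi - p[k]) / d[k]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
      if (t0 > t1) return(NULL)
    }
  }
  rbind(p + t0 * d, p + t1 * d)
}

# clip an open polyline to a rectangle, splitting into the pieces that remain
clip_polyline <- function(xy, r) {
  pieces <- list()
  cur <- NULL
  for (i in seq_len(nrow(xy) - 1)) {
    seg <- clip_segment(xy[i, ], xy[i + 1, ], r)
    if (is.null(seg)) {
      if (!is.null(cur) && nrow(cur) >= 2) pieces <- c(pieces, list(cur))
      cur <- NULL
    } else if (is.null(cur)) {
      cur <- seg
    } else if (sum(abs(cur[nrow(cur), ] - seg[1, ])) < 1e-9) {
      cur <- rbind(cur, seg[2, ])
    } else {
      if (nrow(cur) >= 2) pieces <- c(pieces, list(cur))
      cur <- seg
    }
  }
  if (!is.null(cur) && nrow(cur) >= 2) pieces <- c(pieces, list(cur))
  pieces
}

#' Extract the epithelial-mesenchymal border as a subpixel polyline
#'
#' Traces the zero level set of a level-set field (linear interpolation on the
#' grid, via contour extraction) or, when a binary mask is supplied, of its
#' signed distance transform, which places the border midway between opposite
#' phase pixels rather than on pixel edges. The contour pieces are clipped to
#' the region of interest and the longest open piece connecting the two
#' designated ROI sides is returned, in calibrated micrometers.
#'
#' @param x numeric level-set matrix, or a logical/0-1 mask
#'   (`TRUE`/1 = epithelium).
#' @param pixel_size_um calibration in micrometers per pixel.
#' @param roi region of interest as pixel indices `c(row0, row1, col0, col1)`
#'   (inclusive); default is the full image.
#' @param sides the two ROI sides the border must connect, a subset of
#'   `"left"`, `"right"`, `"top"`, `"bottom"` (default left-right).
#' @param id optional identifier carried into the result.
#' @return object of class `border_polyline`: list with `xy` (vertices in
#'   micrometers), `open = TRUE`, `id` and `roi_um`.
#' @export
extract_border <- function(x, pixel_size_um = 1, roi = NULL,
                           sides = c("left", "right"), id = NULL) {
  stopifnot(is.matrix(x) || is.logical(x))
  sides <- match.arg(sides, c("left", "right", "top", "bottom"),
                     several.ok = TRUE)
  if (length(sides) != 2) stop("`sides` must name exactly two ROI sides",
                               call. = FALSE)
  is_mask <- is.logical(x) || all(x %in% c(0, 1))
  nr <- nrow(x)
  nc <- ncol(x)
  px <- pixel_size_um
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px
  roi_um <- if (is.null(roi)) {
    c(xc[1], xc[nc], yc[1], yc[nr])
  } else {
    c((roi[3] - 1) * px, roi[4] * px, (roi[1] - 1) * px, roi[2] * px)
  }
  if (is_mask) {
    m <- x > 0
    n_in <- sum(m)
    if (n_in == 0 || n_in == length(m)) {
      stop("no border: only one phase present", call. = FALSE)
    }
    dm_fg <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
    dm_bg <- EBImage::imageData(EBImage::distmap(EBImage::Image((!m) * 1)))
    field <- dm_fg - dm_bg
  } else {
    field <- x
  }
  if (!any(field > 0) || !any(field < 0)) {
    stop("no border: the zero level set is empty", call. = FALSE)
  }
  cl <- grDevices::contourLines(x = xc, y = yc, z = t(field), levels = 0)
  if (!length(cl)) stop("no border: the zero level set is empty",
                        call. = FALSE)
  tol <- 0.75 * px
  on_side <- function(p, side) {
    switch(side,
           left = abs(p[1] - roi_um[1]) <= tol,
           right = abs(p[1] - roi_um[2]) <= tol,
           top = abs(p[2] - roi_um[3]) <= tol,
           bottom = abs(p[2] - roi_um[4]) <= tol)
  }
  best <- NULL
  best_len <- -Inf
  n_pieces <- 0L
  for (piece in cl) {
    xy <- cbind(piece$x, piece$y)
    for (sub in clip_polyline(xy, roi_um)) {
      n_pieces <- n_pieces + 1L
      e1 <- sub[1, ]
      e2 <- sub[nrow(sub), ]
      connects <- (on_side(e1, sides[1]) && on_side(e2, sides[2])) ||
        (on_side(e1, sides[2]) && on_side(e2, sides[1]))
      if (!connects) next
      len <- sum(sqrt(rowSums(diff(sub)^2)))
      if (len > best_len) {
        best <- sub
        best_len <- len
      }
    }
  }
  if (is.null(best)) {
    if (n_pieces == 0L) {
      stop("no border: no contour piece crosses the ROI", call. = FALSE)
    }
    stop(sprintf(paste0("border topology error: %d contour piece(s) inside ",
                        "the ROI but none connects the %s and %s sides"),
                 n_pieces, sides[1], sides[2]), call. = FALSE)
  }
  colnames(best) <- c("x_um", "y_um")
  structure(list(xy = best, open = TRUE, id = id, roi_um = roi_um),
            class = "border_polyline")
}

polyline_xy <- function(p) {
  if (inherits(p, "border_polyline")) p$xy
  else if (is.matrix(p) && ncol(p) == 2) p
  else stop("expected a border_polyline or a two-column matrix",
            call. = FALSE)
}

#' Arc length of a polyline
#'
#' Sum of consecutive Euclidean segment lengths; this is the border
#' circumference statistic lambda.
#'
#' @param p a `border_polyline` or two-column matrix of vertices (um).
#' @return arc length in micrometers.
#' @export
curve_length <- function(p) {
  xy <- polyline_xy(p)
  if (nrow(xy) < 2) stop("polyline needs at least 2 vertices", call. = FALSE)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Chord of an open polyline
#'
#' Euclidean distance between the first and last vertex; this is the linear
#' distance statistic d. Undefined for closed curves.
#'
#' @inheritParams curve_length
#' @return chord length in micrometers.
#' @export
linear_distance <- function(p) {
  if (inherits(p, "border_polyline") && !isTRUE(p$open)) {
    stop("`d` is undefined for a closed polyline", call. = FALSE)
  }
  xy <- polyline_xy(p)
  if (nrow(xy) < 2) stop("polyline needs at least 2 vertices", call. = FALSE)
  sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
}

#' Border tortuosity lambda / d
#'
#' The arc length of the border divided by the straight-line distance between
#' its endpoints: the 2-D surface-area proxy. Equals 1 exactly when the border
#' is straight.
#'
#' @inheritParams curve_length
#' @param id,group optional identifier and group label (`"pre"`/`"post"`).
#' @return one-row data frame: `id`, `group`, `lambda_um`, `d_um`, `ratio`.
#' @export
tortuosity <- function(p, id = NULL, group = NA_character_) {
  lam <- curve_length(p)
  d <- linear_distance(p)
  if (d <= 0) {
    stop("degenerate border: endpoints coincide (d = 0)", call. = FALSE)
  }
  if (is.null(id)) {
    id <- if (inherits(p, "border_polyline") && !is.null(p$id)) p$id
    else NA_character_
  }
  data.frame(id = id, group = group, lambda_um = lam, d_um = d,
             ratio = lam / d, stringsAsFactors = FALSE)
}
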