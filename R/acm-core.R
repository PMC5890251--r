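#' @useDynLib emtort, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Regularized Heaviside function
#'
#' Smooth approximation of the unit step used to express region membership in
#' the level-set energy: `H_eps(x) = 1/2 * (1 + (2/pi) * atan(x / epsilon))`.
#' Strictly increasing, with `H_eps(x) + H_eps(-x) = 1` and `H_eps(0) = 1/2`.
#'
#' @param x numeric scalar, vector or matrix (level-set values).
#' @param epsilon positive regularization width, in the units of `x`
#'   (pixel units for the level-set field used here).
#' @return object of the same shape as `x`, values in (0, 1).
#' @export
heaviside_eps <- function(x, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  0.5 * (1 + (2 / pi) * atan(x / epsilon))
}

#' Regularized Dirac delta
#'
#' Derivative of [heaviside_eps()]: `delta_eps(x) = (1/pi) * epsilon /
#' (epsilon^2 + x^2)`. Even in `x`, maximal at 0, unit total integral.
#'
#' @inheritParams heaviside_eps
#' @return object of the same shape as `x`, values > 0.
#' @export
dirac_eps <- function(x, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  (1 / pi) * epsilon / (epsilon^2 + x^2)
}

# derivative of dirac_eps, needed for the exact discrete gradient of the
# length term
ddirac_eps <- function(x, epsilon = 1) {
  -(2 / pi) * epsilon * x / (epsilon^2 + x^2)^2
}

#' Discrete Gaussian kernel
#'
#' Truncated, renormalized Gaussian `K_sigma(x) = exp(-|x|^2 / (2 sigma^2))`
#' on a square support of side `2 * ceiling(truncation * sigma) + 1` pixels,
#' renormalized to sum exactly to 1.
#'
#' @param sigma positive standard deviation in pixels.
#' @param truncation kernel support half-width in units of `sigma` (default 4).
#' @return square numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, truncation = 4) {
  k1 <- gaussian_kernel1d(sigma, truncation)
  k2 <- outer(k1, k1)
  k2 / sum(k2)
}

# 1-D factor of the separable Gaussian, normalized to sum 1
gaussian_kernel1d <- function(sigma, truncation = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  r <- ceiling(truncation * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# zero-padded separable Gaussian smoothing (correlation == convolution for the
# symmetric kernel); `k1` is the normalized 1-D factor
conv_sep <- function(x, k1) {
  storage.mode(x) <- "double"
  sepconv2_cpp(x, as.numeric(k1))
}

#' Parameters of the hybrid active-contour model
#'
#' Bundles every coefficient of the segmentation energy and its gradient-descent
#' evolution. The energy combines two global piecewise-constant (Chan-Vese)
#' data terms weighted `lambda1`/`lambda2`, two kernel-weighted local binary
#' fitting terms weighted `eta1`/`eta2`, and a length-regularization term
#' weighted `nu`. The defaults are local-dominant (`lambda = 0.05`,
#' `eta = 1`): in micrographs with intensity inhomogeneity the two tissue
#' phases are separable locally but not globally, so the local fitting terms
#' carry the evidence and the global terms act only as a weak prior against
#' degenerate labelings.
#'
#' @param lambda1,lambda2 weights of the global inside/outside data terms.
#' @param eta1,eta2 weights of the local inside/outside fitting terms.
#' @param nu weight of the contour-length regularization.
#' @param sigma standard deviation (pixels) of the Gaussian kernel of the
#'   local fitting terms.
#' @param epsilon width (pixels, on the level-set scale) of the regularized
#'   Heaviside/Dirac pair.
#' @param alpha fixed gradient-descent step length.
#' @param max_iter maximum number of iterations (>= 1).
#' @param tol relative energy-change threshold of the stopping rule; descent
#'   stops when the relative change stays below `tol` for `tol_window`
#'   consecutive iterations.
#' @param tol_window number of consecutive sub-threshold iterations required.
#' @param stable_window stop also when the zero level set is stationary: no
#'   pixel of `phi` changes sign for this many consecutive iterations (and at
#'   least `min_iter` iterations have run). The regularized Heaviside has
#'   algebraic tails, so the energy keeps creeping downward as `|phi|` grows
#'   long after the contour has stopped moving; interface stationarity is the
#'   practical convergence signal. Set to `Inf` to rely on the energy rule
#'   alone.
#' @param min_iter minimum number of iterations before the stationarity rule
#'   may fire; protects against declaring convergence while the front is
#'   still eroding a misclassified region (sign flips are rare events early
#'   on because the descent must first drain `|phi|` there).
#' @param kernel_truncation kernel support half-width in sigmas.
#' @param stabilize logical; apply a light Gaussian smoothing to the level-set
#'   field after each descent step. Off by default: the smoothing is a common
#'   stabilizer for local-fitting level sets but it progressively erases
#'   protrusions only a few pixels wide, which are precisely the structures
#'   of interest here; the default runs the verbatim gradient iteration.
#' @param stabilize_sigma standard deviation (pixels) of the stabilizing
#'   smoothing.
#' @param denom_floor floor on the local-fit denominator, as a fraction of the
#'   (unit) kernel mass; pixels below it fall back to the global mean.
#' @return object of class `acm_params`.
#' @export
acm_params <- function(lambda1 = 0.05, lambda2 = 0.05,
                       eta1 = 1, eta2 = 1,
                       nu = 0.1,
                       sigma = 3, epsilon = 1,
                       alpha = 20, max_iter = 200,
                       tol = 1e-6, tol_window = 5, stable_window = 30,
                       min_iter = 50,
                       kernel_truncation = 4,
                       stabilize = FALSE, stabilize_sigma = 0.5,
                       denom_floor = 1e-8) {
  p <- list(lambda1 = lambda1, lambda2 = lambda2, eta1 = eta1, eta2 = eta2,
            nu = nu, sigma = sigma, epsilon = epsilon, alpha = alpha,
            max_iter = max_iter, tol = tol, tol_window = tol_window,
            stable_window = stable_window, min_iter = min_iter,
            kernel_truncation = kernel_truncation,
            stabilize = stabilize, stabilize_sigma = stabilize_sigma,
            denom_floor = denom_floor)
  errs <- character()
  for (nm in c("lambda1", "lambda2", "eta1", "eta2", "nu")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      errs <- c(errs, sprintf("`%s` must be a single finite number >= 0", nm))
    }
  }
  for (nm in c("sigma", "epsilon", "alpha", "tol", "stabilize_sigma",
               "denom_floor")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      errs <- c(errs, sprintf("`%s` must be a single positive number", nm))
    }
  }
  if (!is.numeric(p$max_iter) || length(p$max_iter) != 1L ||
      p$max_iter < 1 || p$max_iter != round(p$max_iter)) {
    errs <- c(errs, "`max_iter` must be an integer >= 1")
  }
  if (!is.numeric(p$tol_window) || p$tol_window < 1) {
    errs <- c(errs, "`tol_window` must be >= 1")
  }
  if (!is.numeric(p$stable_window) || p$stable_window < 1) {
    errs <- c(errs, "`stable_window` must be >= 1")
  }
  if (!is.numeric(p$min_iter) || p$min_iter < 0) {
    errs <- c(errs, "`min_iter` must be >= 0")
  }
  if (!is.logical(p$stabilize) || length(p$stabilize) != 1L) {
    errs <- c(errs, "`stabilize` must be TRUE or FALSE")
  }
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(p, class = "acm_params")
}

# central differences with replicate (edge-clamp) padding
shift_left  <- function(m) m[, c(seq_len(ncol(m))[-1], ncol(m)), drop = FALSE]
shift_right <- function(m) m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
shift_up    <- function(m) m[c(seq_len(nrow(m))[-1], nrow(m)), , drop = FALSE]
shift_down  <- function(m) m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]

grad_central <- function(phi) {
  list(gx = (shift_left(phi) - shift_right(phi)) / 2,
       gy = (shift_up(phi) - shift_down(phi)) / 2)
}

# exact adjoints of the replicate-padded central-difference operators: these
# are what the discrete chain rule produces for the length-term gradient
# (they equal minus the central-difference divergence at interior pixels)
adj_dx <- function(p) {
  nc <- ncol(p)
  out <- matrix(0, nrow(p), nc)
  if (nc >= 2) {
    out[, 2:nc] <- out[, 2:nc] + p[, 1:(nc - 1)]   # from shift_left^T
    out[, nc] <- out[, nc] + p[, nc]
    out[, 1:(nc - 1)] <- out[, 1:(nc - 1)] - p[, 2:nc]  # minus shift_right^T
    out[, 1] <- out[, 1] - p[, 1]
  }
  out / 2
}
adj_dy <- function(p) {
  nr <- nrow(p)
  out <- matrix(0, nr, ncol(p))
  if (nr >= 2) {
    out[2:nr, ] <- out[2:nr, ] + p[1:(nr - 1), ]
    out[nr, ] <- out[nr, ] + p[nr, ]
    out[1:(nr - 1), ] <- out[1:(nr - 1), ] - p[2:nr, ]
    out[1, ] <- out[1, ] - p[1, ]
  }
  out / 2
}
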