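#' Global inside/outside mean intensities
#'
#' Optimal piecewise-constant (Chan-Vese) fit coefficients for the current
#' level-set field: `c1` is the smoothed-Heaviside-weighted mean of the image
#' inside the contour (`phi > 0` side), `c2` the mean outside.
#'
#' @param image numeric matrix of intensities.
#' @param phi level-set field, same shape as `image`.
#' @param epsilon Heaviside regularization width.
#' @return list with scalars `c1` and `c2`.
#' @export
update_global_means <- function(image, phi, epsilon = 1) {
  stopifnot(all(dim(image) == dim(phi)))
  h <- heaviside_eps(phi, epsilon)
  w1 <- sum(h)
  w2 <- sum(1 - h)
  floor_w <- 1e-8 * length(image)
  if (w1 <= floor_w) {
    stop("degenerate phase: inside region (phi > 0) has near-zero mass",
         call. = FALSE)
  }
  if (w2 <= floor_w) {
    stop("degenerate phase: outside region (phi < 0) has near-zero mass",
         call. = FALSE)
  }
  list(c1 = sum(image * h) / w1, c2 = sum(image * (1 - h)) / w2)
}

#' Local inside/outside fitted intensity fields
#'
#' Kernel-weighted local means that accommodate smooth intensity
#' inhomogeneity: `f1 = K * (H(phi) I) / K * H(phi)` and the complementary
#' `f2`, with `K` the truncated Gaussian of [gaussian_kernel()]. Pixels whose
#' denominator falls below `denom_floor` (times the unit kernel mass) take the
#' corresponding global mean as a fallback.
#'
#' @inheritParams update_global_means
#' @param sigma Gaussian kernel standard deviation (pixels).
#' @param truncation kernel support half-width in sigmas.
#' @param denom_floor denominator floor (fraction of kernel mass).
#' @param means optional precomputed result of [update_global_means()].
#' @return list with matrices `f1`, `f2` and fallback pixel counts
#'   `n_fallback1`, `n_fallback2`.
#' @export
update_local_fits <- function(image, phi, epsilon = 1, sigma = 5,
                              truncation = 4, denom_floor = 1e-8,
                              means = NULL) {
  stopifnot(all(dim(image) == dim(phi)))
  if (is.null(means)) means <- update_global_means(image, phi, epsilon)
  k1 <- gaussian_kernel1d(sigma, truncation)
  h <- heaviside_eps(phi, epsilon)
  k_one <- conv_sep(matrix(1, nrow(image), ncol(image)), k1)
  k_img <- conv_sep(image, k1)
  num1 <- conv_sep(h * image, k1)
  den1 <- conv_sep(h, k1)
  num2 <- k_img - num1
  den2 <- k_one - den1
  low1 <- den1 < denom_floor
  low2 <- den2 < denom_floor
  f1 <- ifelse(low1, means$c1, num1 / pmax(den1, denom_floor))
  f2 <- ifelse(low2, means$c2, num2 / pmax(den2, denom_floor))
  list(f1 = f1, f2 = f2,
       n_fallback1 = sum(low1), n_fallback2 = sum(low2))
}

# one coefficient update (Eq. 2 analogue): global means + local fits
update_fit <- function(image, phi, params) {
  means <- update_global_means(image, phi, params$epsilon)
  loc <- update_local_fits(image, phi, params$epsilon, params$sigma,
                           params$kernel_truncation, params$denom_floor,
                           means = means)
  list(c1 = means$c1, c2 = means$c2, f1 = loc$f1, f2 = loc$f2,
       n_fallback = loc$n_fallback1 + loc$n_fallback2)
}
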