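# Small in-code fixtures shared across test files.

# a small random instance for energy/gradient oracles
random_instance <- function(seed, n = 16, eps = 1) {
  set.seed(seed)
  list(image = matrix(runif(n * n), n, n),
       phi = matrix(rnorm(n * n, 0, 1.5), n, n),
       n = n)
}

# a compact pre-branch-like phantom (16 x 24 um -> 80 x 120 px at 0.2 um/px)
small_phantom <- function(seed = 5, noise_sd = 0, ...) {
  phantom_spec("pre_branch", domain_um = c(16, 24),
               baseline = list(y_um = 10), noise_sd = noise_sd,
               seed = seed, ...)
}

# fast ACM parameter set for small tests
fast_params <- function(...) {
  do.call(acm_params,
          utils::modifyList(list(sigma = 3, max_iter = 120), list(...)))
}

# naive, literal term-by-term energy evaluation: double loop over pixel pairs
# for the local terms; the independent oracle for acm_energy
energy_naive <- function(image, phi, fit, params) {
  h <- heaviside_eps(phi, params$epsilon)
  nr <- nrow(image)
  nc <- ncol(image)
  e_g1 <- params$lambda1 * sum((image - fit$c1)^2 * h)
  e_g2 <- params$lambda2 * sum((image - fit$c2)^2 * (1 - h))
  K <- gaussian_kernel(params$sigma, params$kernel_truncation)
  rad <- (nrow(K) - 1) / 2
  e_l1 <- 0
  e_l2 <- 0
  for (ix in seq_len(nr)) {
    for (jx in seq_len(nc)) {
      for (iy in max(1, ix - rad):min(nr, ix + rad)) {
        for (jy in max(1, jx - rad):min(nc, jx + rad)) {
          k <- K[iy - ix + rad + 1, jy - jx + rad + 1]
          e_l1 <- e_l1 + params$eta1 * k *
            (image[iy, jy] - fit$f1[ix, jx])^2 * h[iy, jy]
          e_l2 <- e_l2 + params$eta2 * k *
            (image[iy, jy] - fit$f2[ix, jx])^2 * (1 - h[iy, jy])
        }
      }
    }
  }
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      jp <- min(j + 1, nc); jm <- max(j - 1, 1)
      ip <- min(i + 1, nr); im <- max(i - 1, 1)
      gx[i, j] <- (phi[i, jp] - phi[i, jm]) / 2
      gy[i, j] <- (phi[ip, j] - phi[im, j]) / 2
    }
  }
  e_len <- params$nu * sum(dirac_eps(phi, params$epsilon) *
                             sqrt(gx^2 + gy^2))
  c(total = e_g1 + e_g2 + e_l1 + e_l2 + e_len,
    global1 = e_g1, global2 = e_g2, local1 = e_l1, local2 = e_l2,
    length = e_len)
}

# independently coded two-phase piecewise-constant (Chan-Vese) oracle:
# c-updates, energy and gradient written as explicit loops
cv_oracle <- function(image, phi, params) {
  eps <- params$epsilon
  h <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  d <- (1 / pi) * eps / (eps^2 + phi^2)
  c1 <- sum(image * h) / sum(h)
  c2 <- sum(image * (1 - h)) / sum(1 - h)
  e_g1 <- params$lambda1 * sum((image - c1)^2 * h)
  e_g2 <- params$lambda2 * sum((image - c2)^2 * (1 - h))
  nr <- nrow(image)
  nc <- ncol(image)
  gx <- gy <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      gx[i, j] <- (phi[i, min(j + 1, nc)] - phi[i, max(j - 1, 1)]) / 2
      gy[i, j] <- (phi[min(i + 1, nr), j] - phi[max(i - 1, 1), j]) / 2
    }
  }
  gnorm <- sqrt(gx^2 + gy^2)
  e_len <- params$nu * sum(d * gnorm)
  # gradient: data part + exact derivative of the discrete length term,
  # accumulated by looping over each pixel's dependence on its neighbours
  dd <- -(2 / pi) * eps * phi / (eps^2 + phi^2)^2
  denom <- pmax(gnorm, 1e-10)
  px <- d * gx / denom
  py <- d * gy / denom
  grad <- d * (params$lambda1 * (image - c1)^2 -
                 params$lambda2 * (image - c2)^2) +
    params$nu * dd * gnorm
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      # x-differences that involve phi[i, j]
      acc <- 0
      for (jj in seq_len(nc)) {
        w <- (jj == j - 1 || (jj == nc && j == nc)) -
          (jj == j + 1 || (jj == 1 && j == 1))
        if (w != 0) acc <- acc + w * px[i, jj] / 2
      }
      for (ii in seq_len(nr)) {
        w <- (ii == i - 1 || (ii == nr && i == nr)) -
          (ii == i + 1 || (ii == 1 && i == 1))
        if (w != 0) acc <- acc + w * py[ii, j] / 2
      }
      grad[i, j] <- grad[i, j] + params$nu * acc
    }
  }
  list(c1 = c1, c2 = c2,
       energy = c(total = e_g1 + e_g2 + e_len, global1 = e_g1,
                  global2 = e_g2, length = e_len),
       grad = grad)
}

# central finite differences of the energy at fixed fit coefficients
fd_gradient <- function(image, phi, fit, params, cells, h = 1e-5) {
  vapply(seq_len(nrow(cells)), function(r) {
    i <- cells[r, 1]
    j <- cells[r, 2]
    pp <- phi; pp[i, j] <- pp[i, j] + h
    pm <- phi; pm[i, j] <- pm[i, j] - h
    (acm_energy(image, pp, fit, params)[["total"]] -
        acm_energy(image, pm, fit, params)[["total"]]) / (2 * h)
  }, numeric(1))
}
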