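# Independent oracles and fixture builders shared across tests.

# Direct evaluation of the masked correlation definition:
# G(xi, eta) = mean over overlapping ROI pixel pairs of
#              dIa(x, y) * dIb(x + xi, y + eta) / (mu_a * mu_b),
# computed lag by lag with explicit index shifts (no FFT).
brute_correlation <- function(A, B, roi = NULL, max_lag = 3L) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(A), ncol(A))
  mu_a <- sum(A[roi]) / sum(roi)
  mu_b <- sum(B[roi]) / sum(roi)
  dA <- A - mu_a
  dB <- B - mu_b
  L <- max_lag
  out <- matrix(NA_real_, 2L * L + 1L, 2L * L + 1L)
  nr <- nrow(A); nc <- ncol(A)
  for (eta in -L:L) {
    r1 <- max(1L, 1L - eta):min(nr, nr - eta)
    for (xi in -L:L) {
      c1 <- max(1L, 1L - xi):min(nc, nc - xi)
      m <- roi[r1, c1, drop = FALSE] & roi[r1 + eta, c1 + xi, drop = FALSE]
      n <- sum(m)
      if (n > 0) {
        prod <- dA[r1, c1, drop = FALSE] * dB[r1 + eta, c1 + xi, drop = FALSE]
        out[eta + L + 1L, xi + L + 1L] <- (sum(prod[m]) / n) / (mu_a * mu_b)
      }
    }
  }
  out
}

# Expected distance estimate for particle pairs separated by exactly D:
# the cross-correlation model is the Gaussian PSF autocorrelation
# (e^-1 radius w = 2 * sigma_eff) convolved with a uniform ring of
# radius D, fitted with the same Gaussian model the pipeline uses; the
# expectation is then the same broadening quadrature.
oracle_distance <- function(D, sigma_eff, pixel_size = 10, max_lag = 32,
                            n_angles = 720L) {
  w <- 2 * sigma_eff
  lags <- (-max_lag):max_lag * pixel_size
  th <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  vals <- matrix(0, length(lags), length(lags))
  for (t in th) {
    vals <- vals + exp(-(outer(rep(1, length(lags)), (lags - D * cos(t))^2) +
                           outer((lags - D * sin(t))^2,
                                 rep(1, length(lags)))) / w^2)
  }
  vals <- vals / length(th)
  surf <- structure(
    list(values = vals, lags = (-max_lag):max_lag, pixel_size = pixel_size,
         kind = "cross",
         n_pixels_used = matrix(1, length(lags), length(lags))),
    class = "correlation_surface")
  fit <- fit_correlation(surf)
  stopifnot(fit$converged)
  sqrt(max(0, fit$w_nm^2 - w^2))
}

# Simulate and render both channels on the shared default grid.
render_pair <- function(sim, pixel_size = 10, psf_width = 50) {
  ext <- default_extent(sim$table, psf_width)
  list(
    ch1 = render_image(sim$table, "ch1", pixel_size = pixel_size,
                       psf_width = psf_width, extent = ext),
    ch2 = render_image(sim$table, "ch2", pixel_size = pixel_size,
                       psf_width = psf_width, extent = ext)
  )
}

# Logical disc mask at given centres/radius (nm) on a rendered grid.
disc_mask <- function(img, centers, radius) {
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  cx <- img$origin[1] + (seq_len(nc) - 0.5) * img$pixel_size
  cy <- img$origin[2] + (seq_len(nr) - 0.5) * img$pixel_size
  mk <- matrix(FALSE, nr, nc)
  centers <- as.matrix(centers)
  for (i in seq_len(nrow(centers))) {
    mk <- mk | (outer(rep(1, nr), (cx - centers[i, 1])^2) +
                  outer((cy - centers[i, 2])^2, rep(1, nc))) <= radius^2
  }
  mk
}

# Uniform point table (one localization per particle, no noise): the
# minimal input for density-law and width checks.
uniform_point_table <- function(n, extent_nm, seed) {
  set.seed(seed)
  tibble::tibble(frame = 0L, channel = "ch1",
                 x_nm = runif(n, 0, extent_nm),
                 y_nm = runif(n, 0, extent_nm))
}
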