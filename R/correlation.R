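# Spatial auto-/cross-correlation of image pairs, with ROI-masked
# normalization, and Gaussian model fitting of the resulting surfaces.

pad_fft_size <- function(n, max_lag) {
  stats::nextn(n + max_lag, c(2L, 3L, 5L))
}

#' Spatial correlation surface of two images
#'
#' Computes the normalized spatial (cross-)correlation
#' \deqn{G(\xi,\eta) = \frac{\langle \delta I_a(x,y)\,\delta I_b(x+\xi,
#' y+\eta)\rangle}{\langle I_a\rangle \langle I_b\rangle}}
#' where means and fluctuations \eqn{\delta I = I - \langle I\rangle} are
#' taken over the pixels of the region of interest only. The
#' auto-correlation is the `img_a == img_b` case.
#'
#' Implementation: fluctuation images are zeroed outside the ROI,
#' correlated by zero-padded FFT (no periodic wrap-around), and each lag
#' is normalized by the number of overlapping ROI pixel pairs at that
#' lag, itself obtained by FFT of the mask. This handles both image
#' boundaries and arbitrary ROI shapes uniformly.
#'
#' @param img_a,img_b `rendered_image` objects (or any objects with
#'   `pixels` and `pixel_size`) on the same grid.
#' @param roi Optional logical matrix (same dimensions) selecting the
#'   region of interest; default the full frame.
#' @param max_lag Maximum lag in pixels; the surface covers
#'   `[-max_lag, max_lag]^2` (default 32).
#' @param kind Surface label: `"auto-1"`, `"auto-2"` or `"cross"`.
#' @return A `correlation_surface`: `values` (2*max_lag+1 square matrix,
#'   rows = y-lag eta, cols = x-lag xi), `lags` (pixel lag vector),
#'   `pixel_size`, `kind`, `n_pixels_used` (per-lag overlap counts).
#' @export
compute_correlation <- function(img_a, img_b, roi = NULL, max_lag = 32,
                                kind = "cross") {
  A <- img_a$pixels; B <- img_b$pixels
  if (!all(dim(A) == dim(B))) {
    nc_abort("Images must share grid dimensions.", "grid_mismatch")
  }
  if (!isTRUE(all.equal(img_a$pixel_size, img_b$pixel_size))) {
    nc_abort("Images must share the pixel size.", "grid_mismatch")
  }
  max_lag <- as.integer(max_lag)
  stopifnot(max_lag >= 1L)
  if (is.null(roi)) {
    roi <- matrix(TRUE, nrow(A), ncol(A))
  }
  if (!all(dim(roi) == dim(A))) {
    nc_abort("ROI mask must match the image dimensions.", "grid_mismatch")
  }
  m <- roi * 1.0
  n_roi <- sum(m)
  if (n_roi < (2L * max_lag + 1L)^2) {
    nc_abort("ROI smaller than the lag window.", "insufficient_roi")
  }
  mu_a <- sum(A * m) / n_roi
  mu_b <- sum(B * m) / n_roi
  if (mu_a <= 0 || mu_b <= 0 ||
      sum((A * m - mu_a * m)^2) == 0 || sum((B * m - mu_b * m)^2) == 0) {
    nc_abort("Constant or empty image within the ROI: correlation undefined.",
             "degenerate_input")
  }
  dA <- (A - mu_a) * m
  dB <- (B - mu_b) * m

  P <- c(pad_fft_size(nrow(A), max_lag), pad_fft_size(ncol(A), max_lag))
  padded <- function(x) {
    out <- matrix(0, P[1], P[2])
    out[seq_len(nrow(x)), seq_len(ncol(x))] <- x
    out
  }
  xcorr <- function(u, v) {
    # C(eta, xi) = sum_{x,y} u(y, x) v(y + eta, x + xi)
    Re(fft(Conj(fft(padded(u))) * fft(padded(v)), inverse = TRUE)) /
      prod(P)
  }
  take_lags <- function(C) {
    idx <- function(l, n) ifelse(l >= 0L, l + 1L, n + l + 1L)
    lag <- seq.int(-max_lag, max_lag)
    C[idx(lag, P[1]), idx(lag, P[2]), drop = FALSE]
  }
  num <- take_lags(xcorr(dA, dB))
  cnt <- round(take_lags(xcorr(m, m)))
  vals <- matrix(NA_real_, nrow(num), ncol(num))
  ok <- cnt > 0
  vals[ok] <- (num[ok] / cnt[ok]) / (mu_a * mu_b)

  structure(
    list(values = vals, lags = seq.int(-max_lag, max_lag),
         pixel_size = img_a$pixel_size, kind = kind,
         n_pixels_used = cnt, roi_area = n_roi),
    class = "correlation_surface"
  )
}

#' @export
print.correlation_surface <- function(x, ...) {
  L <- max(x$lags)
  cat(sprintf("<correlation_surface> %s, lags [-%d, %d] px @ %.1f nm/px, G(0,0) = %.4g\n",
              x$kind, L, L, x$pixel_size, x$values[L + 1L, L + 1L]))
  invisible(x)
}

#' Fit a Gaussian model to a correlation surface
#'
#' Least-squares fit of
#' \deqn{G(\xi,\eta) = G_0 \exp\{-(\xi^2+\eta^2)/w^2\} + G_\infty}
#' over the full 2D disc of lags with \eqn{|(\xi,\eta)| \le} `fit_radius`.
#' `w` is the e^-1 radius of the correlation peak, reported in nm via the
#' pixel size (for a channel rendered with Gaussian standard deviation
#' sigma, the autocorrelation width is `w = 2 * sigma`).
#'
#' Starting values: `G_inf` = median of the rim lags, `G_0` =
#' `G(0,0) - G_inf`, `w` = 2 pixels. Non-convergence never raises: the
#' result carries `converged = FALSE` and the best available estimates.
#'
#' @param surface A `correlation_surface`.
#' @param fit_radius Radius in pixels of the fitted lag disc (default:
#'   all available lags).
#' @param include_zero_lag Keep the (0,0) lag in the fit (default `TRUE`;
#'   smooth Gaussian renderings have no shot-noise spike there. Set
#'   `FALSE` for histogram-mode images).
#' @return A `correlation_fit`: `g0`, `w_nm`, `w_px`, `g_inf`,
#'   `residual_rms`, `converged`, `n_points`.
#' @export
fit_correlation <- function(surface, fit_radius = NULL,
                            include_zero_lag = TRUE) {
  L <- max(surface$lags)
  fit_radius <- fit_radius %||% L
  if (fit_radius > L) {
    nc_abort("fit_radius exceeds the computed maximum lag.", "config")
  }
  xi <- matrix(surface$lags, nrow = 2L * L + 1L, ncol = 2L * L + 1L,
               byrow = TRUE)
  eta <- matrix(surface$lags, nrow = 2L * L + 1L, ncol = 2L * L + 1L)
  r2 <- xi^2 + eta^2
  sel <- r2 <= fit_radius^2 & is.finite(surface$values) &
    surface$n_pixels_used > 0
  if (!include_zero_lag) sel[L + 1L, L + 1L] <- FALSE
  if (sum(sel) < 8L) {
    nc_abort("Fewer than 8 lag points available for fitting.", "config")
  }
  g <- surface$values[sel]
  r2v <- r2[sel]

  rim <- sel & sqrt(r2) >= fit_radius - 1
  g_inf0 <- median(surface$values[rim], na.rm = TRUE)
  if (!is.finite(g_inf0)) g_inf0 <- 0
  g00 <- surface$values[L + 1L, L + 1L]
  g0_0 <- g00 - g_inf0
  if (!is.finite(g0_0) || g0_0 == 0) g0_0 <- max(g - g_inf0, 1e-12)

  df <- data.frame(g = g, r2 = r2v)
  # Levenberg-Marquardt from the default 2 px width; wider fallback
  # starts guard against singular gradients when the true peak is broad
  w_starts <- unique(pmax(2, c(2, 5, fit_radius / 4, fit_radius / 2)))
  fit <- NULL
  for (w0 in w_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        g ~ g0 * exp(-r2 / w^2) + ginf, data = df,
        start = list(g0 = g0_0, w = w0, ginf = g_inf0),
        lower = c(g0 = -Inf, w = 1e-3, ginf = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && isTRUE(fit$convInfo$isConv)) break
  }
  if (is.null(fit)) {
    est <- c(g0 = g0_0, w = 2, ginf = g_inf0)
    converged <- FALSE
    resid_rms <- sqrt(mean((g - (est["g0"] * exp(-r2v / est["w"]^2) +
                                   est["ginf"]))^2))
  } else {
    est <- stats::coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
    resid_rms <- sqrt(mean(stats::resid(fit)^2))
  }
  structure(
    list(g0 = unname(est["g0"]),
         w_px = unname(est["w"]),
         w_nm = unname(est["w"]) * surface$pixel_size,
         g_inf = unname(est["ginf"]),
         residual_rms = resid_rms,
         converged = converged,
         negative_amplitude = unname(est["g0"]) < 0,
         n_points = sum(sel),
         kind = surface$kind),
    class = "correlation_fit"
  )
}

#' @export
print.correlation_fit <- function(x, ...) {
  cat(sprintf("<correlation_fit> %s: G0 = %.4g, w = %.1f nm, Ginf = %.3g, RMS = %.3g%s\n",
              x$kind %||% "?", x$g0, x$w_nm, x$g_inf, x$residual_rms,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Radially averaged correlation profile
#'
#' Averages a correlation surface over annuli of integer pixel radius,
#' for display alongside the 2D fits.
#'
#' @param surface A `correlation_surface`.
#' @return Tibble with `r_px`, `r_nm`, `g` (mean over the annulus) and
#'   `n` (lag count).
#' @export
radial_profile <- function(surface) {
  L <- max(surface$lags)
  xi <- matrix(surface$lags, nrow = 2L * L + 1L, ncol = 2L * L + 1L,
               byrow = TRUE)
  eta <- matrix(surface$lags, nrow = 2L * L + 1L, ncol = 2L * L + 1L)
  r <- round(sqrt(xi^2 + eta^2))
  ok <- is.finite(surface$values)
  df <- tibble(r_px = as.vector(r[ok]), g = as.vector(surface$values[ok]))
  out <- dplyr::summarise(dplyr::group_by(df, .data$r_px),
                          g = mean(.data$g), n = dplyr::n(),
                          .groups = "drop")
  out <- out[out$r_px <= L, , drop = FALSE]
  out$r_nm <- out$r_px * surface$pixel_size
  out[, c("r_px", "r_nm", "g", "n")]
}
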