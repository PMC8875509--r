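#' Image cross-correlation spectroscopy of a dual-color image pair
#'
#' Computes the two auto-correlations and the cross-correlation of the
#' rendered channel pair, fits the Gaussian model to each, and derives:
#'
#' * the amplitude-ratio colocalization coefficients
#'   `M1 = G0_cross / G0_auto2` (fraction of channel-1 particles with a
#'   channel-2 partner) and `M2 = G0_cross / G0_auto1`;
#' * the colocalized fraction `f_ICCS = (M1 + M2) / 2`;
#' * the correlation distance
#'   `d = sqrt(max(0, w_cross^2 - (w_auto1^2 + w_auto2^2) / 2))` in nm,
#'   from the broadening of the cross-correlation relative to the pooled
#'   auto-correlation width (set to 0, with a flag, when the cross peak
#'   is not broader — negative broadening is noise).
#'
#' `M1`/`M2` are reported raw (noisy fits can exceed 1); clamped
#' convenience values in `[0, 1]` are attached alongside.
#'
#' @param img_1,img_2 `rendered_image` objects on a shared grid.
#' @param roi Optional logical ROI mask (e.g. a nucleus) applied to all
#'   three correlations.
#' @param max_lag Maximum correlation lag in pixels (default 32, i.e.
#'   320 nm at 10 nm/pixel — several times the expected correlation
#'   width).
#' @param fit_radius Lag-disc radius for the fits (default `max_lag`).
#' @param include_zero_lag Passed to [fit_correlation()].
#' @return An `iccs_result`: `M1`, `M2`, `M1_clamped`, `M2_clamped`,
#'   `f_iccs`, `f_iccs_clamped`, `d_nm`, `d_floored` (cross not broader
#'   than autos), `valid`, `fits` (list `auto1`, `auto2`, `cross`),
#'   `roi_area`, `params`.
#' @export
compute_iccs <- function(img_1, img_2, roi = NULL, max_lag = 32,
                         fit_radius = NULL, include_zero_lag = TRUE) {
  fit_radius <- fit_radius %||% max_lag
  s_a1 <- compute_correlation(img_1, img_1, roi = roi, max_lag = max_lag,
                              kind = "auto-1")
  s_a2 <- compute_correlation(img_2, img_2, roi = roi, max_lag = max_lag,
                              kind = "auto-2")
  s_x <- compute_correlation(img_1, img_2, roi = roi, max_lag = max_lag,
                             kind = "cross")
  f_a1 <- fit_correlation(s_a1, fit_radius, include_zero_lag)
  f_a2 <- fit_correlation(s_a2, fit_radius, include_zero_lag)
  f_x <- fit_correlation(s_x, fit_radius, include_zero_lag)

  valid <- f_a1$converged && f_a2$converged
  clamp01 <- function(v) min(max(v, 0), 1)

  if (valid && f_x$converged) {
    M1 <- f_x$g0 / f_a2$g0
    M2 <- f_x$g0 / f_a1$g0
    f <- (M1 + M2) / 2
    w2_pool <- (f_a1$w_nm^2 + f_a2$w_nm^2) / 2
    broadening <- f_x$w_nm^2 - w2_pool
    d <- sqrt(max(0, broadening))
    d_floored <- broadening <= 0
  } else if (valid) {
    # autos fine, cross fit failed: no detectable correlation
    M1 <- M2 <- f <- 0
    d <- NA_real_
    d_floored <- NA
  } else {
    M1 <- M2 <- f <- NA_real_
    d <- NA_real_
    d_floored <- NA
  }

  structure(
    list(M1 = M1, M2 = M2,
         M1_clamped = if (is.na(M1)) NA_real_ else clamp01(M1),
         M2_clamped = if (is.na(M2)) NA_real_ else clamp01(M2),
         f_iccs = f,
         f_iccs_clamped = if (is.na(f)) NA_real_ else clamp01(f),
         d_nm = d, d_floored = d_floored,
         valid = valid,
         cross_converged = f_x$converged,
         fits = list(auto1 = f_a1, auto2 = f_a2, cross = f_x),
         surfaces = list(auto1 = s_a1, auto2 = s_a2, cross = s_x),
         roi_area = s_x$roi_area,
         params = list(max_lag = max_lag, fit_radius = fit_radius,
                       pixel_size = img_1$pixel_size,
                       psf_width = img_1$psf_width %||% NA_real_,
                       include_zero_lag = include_zero_lag)),
    class = "iccs_result"
  )
}

#' @export
print.iccs_result <- function(x, ...) {
  cat("<iccs_result>\n")
  if (!x$valid) {
    cat("  INVALID: an auto-correlation fit did not converge\n")
  } else {
    cat(sprintf("  f_ICCS = %.3f  (M1 = %.3f, M2 = %.3f)\n",
                x$f_iccs, x$M1, x$M2))
    if (is.na(x$d_nm)) {
      cat("  d undefined (cross-correlation fit not converged)\n")
    } else {
      cat(sprintf("  d = %.1f nm%s\n", x$d_nm,
                  if (isTRUE(x$d_floored)) " (floored: cross peak not broader than autos)" else ""))
    }
  }
  cat(sprintf("  ROI: %d px; max lag %d px @ %.1f nm/px\n",
              x$roi_area, x$params$max_lag, x$params$pixel_size))
  invisible(x)
}

#' Local colocalization map by sliding-window ICCS
#'
#' Runs [compute_iccs()] on square subregions tiling the image (window
#' `window` pixels, stride `step`) and maps the local `f_ICCS` and `d`
#' at each subregion centre. Cells whose subregion has less than 25% ROI
#' coverage, or whose fits fail, are marked invalid.
#'
#' @param img_1,img_2 `rendered_image` objects on a shared grid.
#' @param window Odd subregion side in pixels (default 69).
#' @param step Stride between subregions (default `floor(window / 2)`).
#' @param roi Optional logical ROI mask.
#' @param max_lag Per-subregion maximum lag; capped at
#'   `floor((window - 1) / 2)` so the lag window fits the subregion.
#' @param min_coverage Minimum ROI fraction for a valid cell (default
#'   0.25).
#' @return A `coloc_map`: matrices `f_map`, `d_map`, `valid`, plus the
#'   subregion centre coordinates (`centers_x_nm`, `centers_y_nm`) and
#'   geometry fields.
#' @export
local_iccs <- function(img_1, img_2, window = 69, step = NULL, roi = NULL,
                       max_lag = 32, min_coverage = 0.25) {
  window <- as.integer(window)
  if (window %% 2L == 0L) {
    nc_abort("`window` must be odd.", "config")
  }
  dims <- dim(img_1$pixels)
  if (window > min(dims)) {
    nc_abort("`window` exceeds the image dimensions.", "size")
  }
  step <- as.integer(step %||% max(1L, window %/% 2L))
  lag <- min(as.integer(max_lag), (window - 1L) %/% 2L)
  if (is.null(roi)) roi <- matrix(TRUE, dims[1], dims[2])

  r0 <- seq.int(1L, dims[1] - window + 1L, by = step)
  c0 <- seq.int(1L, dims[2] - window + 1L, by = step)
  f_map <- matrix(NA_real_, length(r0), length(c0))
  d_map <- matrix(NA_real_, length(r0), length(c0))
  valid <- matrix(FALSE, length(r0), length(c0))

  sub_img <- function(img, rr, cc) {
    out <- img
    out$pixels <- img$pixels[rr, cc, drop = FALSE]
    out
  }
  for (i in seq_along(r0)) {
    rr <- r0[i]:(r0[i] + window - 1L)
    for (j in seq_along(c0)) {
      cc <- c0[j]:(c0[j] + window - 1L)
      sub_roi <- roi[rr, cc, drop = FALSE]
      if (mean(sub_roi) < min_coverage) next
      res <- tryCatch(
        compute_iccs(sub_img(img_1, rr, cc), sub_img(img_2, rr, cc),
                     roi = if (all(sub_roi)) NULL else sub_roi,
                     max_lag = lag),
        nanocoloc_error = function(e) NULL
      )
      if (is.null(res) || !res$valid) next
      f_map[i, j] <- res$f_iccs
      d_map[i, j] <- res$d_nm
      valid[i, j] <- TRUE
    }
  }
  half <- (window - 1L) / 2
  structure(
    list(f_map = f_map, d_map = d_map, valid = valid,
         centers_x_nm = img_1$origin[1] + (c0 + half - 0.5) * img_1$pixel_size,
         centers_y_nm = img_1$origin[2] + (r0 + half - 0.5) * img_1$pixel_size,
         window = window, step = step, max_lag = lag,
         pixel_size = img_1$pixel_size),
    class = "coloc_map"
  )
}

#' @export
print.coloc_map <- function(x, ...) {
  cat(sprintf("<coloc_map> %d x %d cells (window %d px, step %d px): %d valid\n",
              nrow(x$f_map), ncol(x$f_map), x$window, x$step, sum(x$valid)))
  if (any(x$valid)) {
    cat(sprintf("  f_ICCS: mean %.3f; d: mean %.1f nm (valid cells)\n",
                mean(x$f_map[x$valid]),
                mean(x$d_map[x$valid], na.rm = TRUE)))
  }
  invisible(x)
}
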