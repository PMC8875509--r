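# broom-style tidiers for fitted objects

#' Tidy a correlation fit
#'
#' @param x A `correlation_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.correlation_fit <- function(x, ...) {
  tibble(term = c("g0", "w_nm", "g_inf"),
         estimate = c(x$g0, x$w_nm, x$g_inf))
}

#' @rdname tidy.correlation_fit
#' @export
glance.correlation_fit <- function(x, ...) {
  tibble(g0 = x$g0, w_nm = x$w_nm, g_inf = x$g_inf,
         residual_rms = x$residual_rms, converged = x$converged,
         n_points = x$n_points)
}

#' Tidy an ICCS result
#'
#' `tidy()` gives one row per correlation component (the two autos and
#' the cross) with its fitted Gaussian parameters; `glance()` gives the
#' one-row summary with the colocalization coefficients and distance.
#'
#' @param x An `iccs_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.iccs_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(component = c("auto1", "auto2", "cross")),
    dplyr::bind_rows(lapply(x$fits[c("auto1", "auto2", "cross")], glance))
  )
}

#' @rdname tidy.iccs_result
#' @export
glance.iccs_result <- function(x, ...) {
  tibble(f_iccs = x$f_iccs, f_iccs_clamped = x$f_iccs_clamped,
         M1 = x$M1, M2 = x$M2, d_nm = x$d_nm,
         d_floored = x$d_floored, valid = x$valid,
         roi_area = x$roi_area)
}

#' Tidy a 2D transform
#'
#' @param x A `transform2d`.
#' @param ... Unused.
#' @return One row per matrix entry (`term`, `estimate`) plus the RMS
#'   residual row.
#' @export
tidy.transform2d <- function(x, ...) {
  m <- x$matrix
  tibble(term = c("a11", "a12", "tx", "a21", "a22", "ty", "rms_residual"),
         estimate = c(m[1, 1], m[1, 2], m[1, 3],
                      m[2, 1], m[2, 2], m[2, 3], x$rms_residual))
}
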