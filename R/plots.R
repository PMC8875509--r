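# ggplot2 display methods for result objects

#' Radial correlation curves of an ICCS result
#'
#' The two auto-correlations and the cross-correlation, radially
#' averaged, with the fitted Gaussian models overlaid — the standard way
#' of inspecting whether the amplitude ratios and the cross broadening
#' are supported by the data.
#'
#' @param object An `iccs_result` (with surfaces attached).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iccs_result <- function(object, ...) {
  profs <- dplyr::bind_rows(lapply(names(object$surfaces), function(k) {
    p <- radial_profile(object$surfaces[[k]])
    p$component <- k
    p
  }))
  fits <- dplyr::bind_rows(lapply(names(object$fits), function(k) {
    f <- object$fits[[k]]
    r <- seq(0, max(profs$r_nm), length.out = 200)
    tibble(r_nm = r,
           g = f$g0 * exp(-(r / f$w_nm)^2) + f$g_inf,
           component = k)
  }))
  ggplot2::ggplot(profs, ggplot2::aes(.data$r_nm, .data$g,
                                      colour = .data$component)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_line(data = fits) +
    ggplot2::labs(x = expression(paste("lag ", xi, " (nm)")),
                  y = expression(G(xi)),
                  colour = NULL, title = "ICCS correlation functions")
}

#' Map view of a local colocalization analysis
#'
#' @param object A `coloc_map`.
#' @param which `"f"` (colocalized fraction, default) or `"d"`
#'   (correlation distance).
#' @param ... Unused.
#' @return A ggplot raster of valid cells.
#' @export
autoplot.coloc_map <- function(object, which = c("f", "d"), ...) {
  which <- match.arg(which)
  m <- if (which == "f") object$f_map else object$d_map
  df <- expand.grid(y = object$centers_y_nm, x = object$centers_x_nm)
  df$value <- as.vector(m)
  df$value[!as.vector(object$valid)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(
      name = if (which == "f") expression(f[ICCS]) else "d (nm)",
      na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = "Local colocalization map")
}
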