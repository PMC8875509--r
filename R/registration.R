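# Landmark-based registration of confocal images to the SMLM frame,
# focus segmentation, mask transfer, and mask-restricted ICCS.

#' Estimate a 2D transform from matched landmark pairs
#'
#' Least-squares mapping of `src_points` onto `dst_points` (both n x 2
#' matrices or data frames of nm coordinates, matched row-wise). Models:
#' `"translation"` (>= 1 pair), `"similarity"` — translation + rotation +
#' isotropic scale, closed-form Procrustes/Umeyama solution (>= 2 pairs,
#' the default: confocal and widefield share the objective so shear is
#' not expected) — and `"affine"` (>= 3 non-collinear pairs).
#'
#' @param src_points,dst_points Matched coordinate sets (nm).
#' @param model `"similarity"`, `"translation"` or `"affine"`.
#' @return A `transform2d`: `model`, `matrix` (2 x 3, mapping
#'   `(x, y, 1)` in the source frame to the destination frame),
#'   `rms_residual` (nm).
#' @export
estimate_transform <- function(src_points, dst_points,
                               model = c("similarity", "translation",
                                         "affine")) {
  model <- match.arg(model)
  src <- as.matrix(as.data.frame(src_points))[, 1:2, drop = FALSE]
  dst <- as.matrix(as.data.frame(dst_points))[, 1:2, drop = FALSE]
  storage.mode(src) <- storage.mode(dst) <- "double"
  n <- nrow(src)
  if (nrow(dst) != n) {
    nc_abort("Point lists must have the same length.", "config")
  }
  min_n <- c(translation = 1L, similarity = 2L, affine = 3L)[[model]]
  if (n < min_n) {
    nc_abort(paste0("Model '", model, "' needs at least ", min_n,
                    " point pair(s)."), "config")
  }

  if (model == "translation") {
    t <- colMeans(dst - src)
    M <- cbind(diag(2), t)
  } else if (model == "similarity") {
    mu_s <- colMeans(src); mu_d <- colMeans(dst)
    S <- sweep(src, 2, mu_s); D <- sweep(dst, 2, mu_d)
    var_s <- sum(S^2) / n
    if (var_s == 0) nc_abort("Degenerate source geometry (coincident points).",
                             "degenerate_geometry")
    Sigma <- crossprod(D, S) / n
    sv <- svd(Sigma)
    sgn <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
    R <- sv$u %*% sgn %*% t(sv$v)
    s <- sum(diag(sgn) * sv$d) / var_s
    t <- mu_d - s * R %*% mu_s
    M <- cbind(s * R, t)
  } else {
    X <- cbind(src, 1)
    if (qr(X)$rank < 3L) {
      nc_abort("Collinear landmarks: affine transform is ill-conditioned.",
               "degenerate_geometry")
    }
    coefs <- qr.solve(X, dst)       # 3 x 2
    M <- t(coefs)[, c(1, 2, 3), drop = FALSE]
  }
  if (abs(det(M[, 1:2])) < 1e-12) {
    nc_abort("Estimated transform is singular.", "degenerate_geometry")
  }
  pred <- t(M %*% t(cbind(src, 1)))
  rms <- sqrt(mean(rowSums((pred - dst)^2)))
  structure(list(model = model, matrix = M, rms_residual = rms),
            class = "transform2d")
}

#' Apply a 2D transform to points
#'
#' @param points n x 2 matrix or data frame of (x, y) nm.
#' @param transform A `transform2d`.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(points, transform) {
  p <- as.matrix(as.data.frame(points))[, 1:2, drop = FALSE]
  out <- t(transform$matrix %*% t(cbind(p, 1)))
  colnames(out) <- c("x", "y")
  out
}

#' Invert a 2D transform
#'
#' @param transform A `transform2d`.
#' @return The inverse `transform2d` (residual not defined, set 0).
#' @export
invert_transform <- function(transform) {
  A <- transform$matrix[, 1:2]
  t <- transform$matrix[, 3]
  Ai <- solve(A)
  structure(list(model = transform$model,
                 matrix = cbind(Ai, -Ai %*% t),
                 rms_residual = 0),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d> %s, RMS residual %.2f nm\n", x$model,
              x$rms_residual))
  print(round(x$matrix, 6))
  invisible(x)
}

new_mask <- function(pixels, pixel_size, origin = c(0, 0)) {
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "nc_mask")
}

#' @export
print.nc_mask <- function(x, ...) {
  cat(sprintf("<mask> %d x %d px @ %.1f nm/px, %d set (%.1f%%)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

#' Segment bright foci in a diffraction-limited image
#'
#' Global threshold (Otsu by default) followed by connected-component
#' labelling; components smaller than `min_area` pixels are discarded.
#' Border-touching components are retained.
#'
#' @param image A `confocal_image` (or matrix with `pixel_size`,
#'   `origin` supplied).
#' @param min_area Minimum component area in pixels (default 20).
#' @param threshold_method `"otsu"` (default) or a numeric threshold on
#'   the raw intensity scale.
#' @param pixel_size,origin Grid geometry, when `image` is a bare
#'   matrix.
#' @return An `nc_mask` on the image grid; `n_components` attribute
#'   gives the surviving focus count. Empty mask (with a warning) when
#'   nothing survives.
#' @export
segment_foci <- function(image, min_area = 20, threshold_method = "otsu",
                         pixel_size = NULL, origin = NULL) {
  if (is.matrix(image)) {
    image <- new_confocal_image(image, pixel_size %||% 1,
                                origin %||% c(0, 0))
  }
  px <- image$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    nc_abort("Constant image: cannot segment.", "degenerate_input")
  }
  if (identical(threshold_method, "otsu")) {
    scaled <- (px - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    bin <- scaled > th
  } else if (is.numeric(threshold_method)) {
    bin <- px > threshold_method
  } else {
    nc_abort("Unknown threshold method.", "config")
  }
  labels <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- as.integer(EBImage::imageData(labels))
  areas <- tabulate(lab)
  keep <- which(areas >= min_area)
  mask <- matrix(lab %in% keep, nrow(px), ncol(px))
  if (length(keep) == 0L) {
    nc_warn("No component survived the area filter: empty mask.",
            "empty_mask")
  }
  out <- new_mask(mask, image$pixel_size, image$origin)
  attr(out, "n_components") <- length(keep)
  out
}

#' Resample a mask onto a rendered-image grid through a transform
#'
#' Maps the mask (e.g. segmented confocal foci) into the SMLM coordinate
#' frame: every target pixel centre is pulled back through the inverse
#' transform and looked up in the source mask by nearest neighbour.
#'
#' @param mask An `nc_mask` in the source (e.g. confocal) frame.
#' @param transform `transform2d` mapping source-frame nm to
#'   target-frame nm.
#' @param target A `rendered_image` (or mask) defining the output grid.
#' @return An `nc_mask` aligned with `target`.
#' @export
transfer_mask <- function(mask, transform, target) {
  inv <- invert_transform(transform)
  nr <- nrow(target$pixels); ncl <- ncol(target$pixels)
  cx <- target$origin[1] + (seq_len(ncl) - 0.5) * target$pixel_size
  cy <- target$origin[2] + (seq_len(nr) - 0.5) * target$pixel_size
  pts <- cbind(rep(cx, each = nr), rep(cy, times = ncl))
  src <- apply_transform(pts, inv)
  col_idx <- floor((src[, 1] - mask$origin[1]) / mask$pixel_size) + 1L
  row_idx <- floor((src[, 2] - mask$origin[2]) / mask$pixel_size) + 1L
  inside <- col_idx >= 1L & col_idx <= ncol(mask$pixels) &
    row_idx >= 1L & row_idx <= nrow(mask$pixels)
  vals <- logical(nr * ncl)
  vals[inside] <- mask$pixels[cbind(row_idx[inside], col_idx[inside])]
  out <- new_mask(matrix(vals, nr, ncl), target$pixel_size, target$origin)
  if (!any(out$pixels)) {
    nc_warn("Transform maps the mask entirely outside the target grid.",
            "empty_mask")
  }
  out
}

#' ICCS restricted to a mask region
#'
#' Delegates to [compute_iccs()] with the mask as ROI — the standard
#' comparison of colocalization inside segmented foci against the whole
#' nucleus. The result additionally records the mask coverage
#' fraction.
#'
#' @param img_1,img_2 `rendered_image` objects on a shared grid.
#' @param mask An `nc_mask` on the same grid (use [transfer_mask()]
#'   first for confocal-frame masks), or a logical matrix.
#' @param ... Passed to [compute_iccs()].
#' @return An `iccs_result` with a `mask_coverage` field.
#' @export
masked_iccs <- function(img_1, img_2, mask, ...) {
  px <- if (is.matrix(mask)) mask else mask$pixels
  if (!all(dim(px) == dim(img_1$pixels))) {
    nc_abort("Mask grid does not match the images; transfer it first.",
             "grid_mismatch")
  }
  if (!any(px)) nc_abort("Empty mask.", "insufficient_roi")
  res <- compute_iccs(img_1, img_2, roi = px, ...)
  res$mask_coverage <- mean(px)
  res
}
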