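similarity_points <- function(n, theta_deg = 7, scale = 1.02,
                              shift = c(120, -80), seed = 61) {
  set.seed(seed)
  src <- cbind(runif(n, 0, 2e4), runif(n, 0, 2e4))
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  dst <- t(scale * R %*% t(src)) + matrix(rep(shift, each = n), n, 2)
  list(src = src, dst = dst)
}

test_that("identity and known transforms are recovered exactly", {
  pts <- similarity_points(4)
  id <- estimate_transform(pts$src, pts$src, "similarity")
  expect_equal(id$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-9)
  expect_equal(id$rms_residual, 0, tolerance = 1e-9)

  tf <- estimate_transform(pts$src, pts$dst, "similarity")
  expect_equal(max(abs(apply_transform(pts$src, tf) - pts$dst)), 0,
               tolerance = 1e-9)
  lin <- tf$matrix[, 1:2]
  expect_equal(sqrt(det(lin)), 1.02, tolerance = 1e-9)       # isotropic scale
  expect_equal(atan2(lin[2, 1], lin[1, 1]) * 180 / pi, 7,
               tolerance = 1e-9)                             # rotation angle
  expect_equal(crossprod(lin / 1.02), diag(2), tolerance = 1e-9) # no shear

  tr <- estimate_transform(cbind(0, 0), cbind(5, -3), "translation")
  expect_equal(apply_transform(cbind(10, 10), tr), cbind(x = 15, y = 7))

  aff <- estimate_transform(pts$src, pts$dst, "affine")
  expect_equal(max(abs(apply_transform(pts$src, aff) - pts$dst)), 0,
               tolerance = 1e-8)
})

test_that("degenerate landmark geometry is rejected", {
  col <- cbind(1:4, 2 * (1:4))
  expect_error(estimate_transform(col, col + 1, "affine"),
               class = "nanocoloc_error_degenerate_geometry")
  same <- cbind(rep(1, 3), rep(1, 3))
  expect_error(estimate_transform(same, same + 1, "similarity"),
               class = "nanocoloc_error_degenerate_geometry")
  expect_error(estimate_transform(cbind(1, 1), cbind(1, 2), "similarity"),
               class = "nanocoloc_error_config")
})

test_that("residuals under landmark noise match least-squares theory", {
  # dst noise sd sigma per coordinate; similarity uses k = 4 of the 2n
  # coordinate equations, so E[RSS] = sigma^2 (2n - k) and the per-point
  # 2D rms is sigma * sqrt(2 - k / n)
  sigma <- 20; n <- 6
  rms <- vapply(1:100, function(s) {
    pts <- similarity_points(n, seed = 600 + s)
    noisy <- pts$dst + matrix(rnorm(2 * n, 0, sigma), n, 2)
    estimate_transform(pts$src, noisy, "similarity")$rms_residual
  }, double(1))
  expect_equal(mean(rms), sigma * sqrt(2 - 4 / n), tolerance = 0.1)
})

test_that("bright foci are segmented with area filtering", {
  set.seed(62)
  img <- matrix(10, 100, 100)
  ctr <- cbind(c(20, 50, 80, 30, 70), c(20, 40, 15, 80, 75))
  for (i in 1:5) {
    for (r in 1:100) for (c in 1:100) {
      if ((r - ctr[i, 1])^2 + (c - ctr[i, 2])^2 <= 16) img[r, c] <- 100
    }
  }
  img <- img + rnorm(1e4)
  seg <- segment_foci(img, min_area = 10, pixel_size = 70)
  expect_equal(attr(seg, "n_components"), 5L)

  # large min_area: nothing survives on a noise-only image
  noise <- matrix(10 + rnorm(2500), 50, 50)
  expect_warning(seg2 <- segment_foci(noise, min_area = 2000,
                                      pixel_size = 70),
                 class = "nanocoloc_warning_empty_mask")
  expect_equal(sum(seg2$pixels), 0L)

  # border-touching focus is retained
  bimg <- matrix(10, 50, 50)
  for (r in 1:50) for (c in 1:50) {
    if ((r - 1)^2 + (c - 25)^2 <= 16) bimg[r, c] <- 100
  }
  seg3 <- segment_foci(bimg, min_area = 5, pixel_size = 70)
  expect_equal(attr(seg3, "n_components"), 1L)

  expect_error(segment_foci(matrix(3, 10, 10), pixel_size = 70),
               class = "nanocoloc_error_degenerate_input")
})

test_that("mask transfer respects exact and near-exact geometry", {
  set.seed(63)
  px <- matrix(runif(400) > 0.7, 20, 20)
  mask <- nanocoloc:::new_mask(px, 10, c(0, 0))
  target <- list(pixels = matrix(0, 20, 20), pixel_size = 10,
                 origin = c(0, 0))
  idpts <- cbind(c(0, 100, 0), c(0, 0, 100))
  ident <- estimate_transform(idpts, idpts, "similarity")
  expect_identical(transfer_mask(mask, ident, target)$pixels, px)

  # integer-pixel translation shifts the mask exactly
  shift <- estimate_transform(idpts, idpts + 30, "translation")
  shifted <- transfer_mask(mask, shift, target)$pixels
  expect_identical(shifted[4:20, 4:20], px[1:17, 1:17])
  expect_true(all(!shifted[1:3, ]))

  # 90 degree rotation of an L-shape conserves area to within 2%
  L <- matrix(FALSE, 40, 40)
  L[10:30, 10:14] <- TRUE
  L[26:30, 10:26] <- TRUE
  lmask <- nanocoloc:::new_mask(L, 10, c(0, 0))
  th <- pi / 2
  src <- cbind(c(0, 400, 0), c(0, 0, 400))
  ctr <- c(200, 200)
  rot <- t(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
             t(sweep(src, 2, ctr))) + matrix(rep(ctr, each = 3), 3, 2)
  tf <- estimate_transform(src, rot, "similarity")
  big_target <- list(pixels = matrix(0, 40, 40), pixel_size = 10,
                     origin = c(0, 0))
  out <- transfer_mask(lmask, tf, big_target)
  expect_lt(abs(sum(out$pixels) - sum(L)) / sum(L), 0.02)

  # transform mapping far away: empty with warning
  far <- estimate_transform(idpts, idpts + 1e6, "translation")
  expect_warning(transfer_mask(mask, far, target),
                 class = "nanocoloc_warning_empty_mask")
})

test_that("transform round-trip matches the generating transform on masks", {
  pts <- similarity_points(5, seed = 64)
  tf_true <- estimate_transform(pts$src, pts$dst, "similarity")
  tf_est <- estimate_transform(pts$src, apply_transform(pts$src, tf_true),
                               "similarity")
  set.seed(65)
  px <- matrix(runif(900) > 0.6, 30, 30)
  mask <- nanocoloc:::new_mask(px, 70, c(0, 0))
  target <- list(pixels = matrix(0, 120, 120), pixel_size = 20,
                 origin = c(-500, -500))
  expect_identical(transfer_mask(mask, tf_est, target)$pixels,
                   transfer_mask(mask, tf_true, target)$pixels)
})

test_that("masking with the full frame reproduces the unmasked analysis", {
  sim <- simulate_dataset(sim_config(
    extent = c(4000, 4000), n_particles_1 = 400, n_particles_2 = 400,
    f_true = 0.5, pair_distance = 0, seed = 66))
  imgs <- render_pair(sim)
  plain <- compute_iccs(imgs$ch1, imgs$ch2, max_lag = 16)
  full <- matrix(TRUE, nrow(imgs$ch1$pixels), ncol(imgs$ch1$pixels))
  masked <- masked_iccs(imgs$ch1, imgs$ch2, full, max_lag = 16)
  expect_identical(masked$f_iccs, plain$f_iccs)
  expect_identical(masked$d_nm, plain$d_nm)
  expect_identical(masked$fits$cross$g0, plain$fits$cross$g0)
  expect_identical(masked$surfaces$auto1$values, plain$surfaces$auto1$values)
  expect_equal(masked$mask_coverage, 1)

  # a mask over empty space is degenerate
  empty_zone <- matrix(FALSE, nrow(full), ncol(full))
  empty_zone[1:40, 1:40] <- TRUE
  ring_img <- imgs$ch1
  ring_img$pixels[1:40, 1:40] <- 0
  expect_error(masked_iccs(ring_img, ring_img, empty_zone, max_lag = 8),
               class = "nanocoloc_error_degenerate_input")
})

test_that("foci-restricted analysis exceeds the whole-field estimate", {
  ok <- 0L
  for (s in 1:5) {
    cfg <- sim_config(extent = c(6000, 6000), n_particles_1 = 800,
                      n_particles_2 = 800, pair_distance = 0, seed = 70 + s)
    fc <- cbind(runif(5, 800, 5200), runif(5, 800, 5200))
    sim <- simulate_composite_dataset(cfg, fc, foci_radius = 500,
                                      f_inside = 0.8, f_outside = 0.1)
    imgs <- render_pair(sim)
    mk <- disc_mask(imgs$ch1, fc, 500)
    g <- compute_iccs(imgs$ch1, imgs$ch2)
    m <- masked_iccs(imgs$ch1, imgs$ch2, mk)
    if (m$f_iccs > g$f_iccs) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})
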