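sim_drifted <- function(seed, drift_model = "random_walk",
                        n_particles = 200, loc_precision = 10,
                        n_fiducials = 3, keyframe = 1L, ...) {
  simulate_dataset(sim_config(
    extent = c(10000, 10000), n_particles_1 = n_particles,
    n_particles_2 = n_particles, f_true = 0,
    loc_precision = loc_precision, drift_model = drift_model,
    n_fiducials = n_fiducials, fiducial_keyframe_interval = keyframe,
    seed = seed, ...))
}

channel_table <- function(sim, ch = "ch1") {
  out <- sim$table[sim$table$channel == ch, , drop = FALSE]
  attr(out, "n_frames") <- n_frames(sim$table)
  out
}

test_that("persistent emitters are found among blinking molecules", {
  sim <- sim_drifted(51, drift_model = "none", keyframe = 1L)
  tab <- channel_table(sim)
  tr <- suppressWarnings(detect_fiducials(tab, capture_radius = 100,
                                          min_occupancy = 0.8))
  expect_equal(nrow(tr), 3L)
  expect_true(all(tr$occupancy > 0.99))
  # recovered positions match the planted fiducials
  d <- vapply(seq_len(3), function(i) {
    min(sqrt((tr$x_nm - sim$truth$fiducials$x_nm[i])^2 +
               (tr$y_nm - sim$truth$fiducials$y_nm[i])^2))
  }, double(1))
  expect_true(all(d < 20))
})

test_that("tables without fiducials yield an empty track set", {
  sim <- sim_drifted(52, drift_model = "none", n_fiducials = 0)
  tr <- detect_fiducials(channel_table(sim), 100, 0.5)
  expect_equal(nrow(tr), 0L)
})

test_that("keyframe-sampled fiducials are detected over keyframes", {
  sim <- sim_drifted(53, drift_model = "none", keyframe = 1000L)
  tab <- channel_table(sim)
  # occupancy over all frames would be ~15/15000; over keyframes it is 1
  none <- detect_fiducials(tab, 100, 0.5, keyframe_interval = 1L)
  some <- detect_fiducials(tab, 100, 0.5, keyframe_interval = 1000L)
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(some), 3L)
})

test_that("noiseless linear drift is recovered exactly", {
  pos <- tibble::tibble(frame = 0:999, x_nm = 5000 + frame / 100,
                        y_nm = 3000)
  tracks <- tibble::tibble(id = 1L, x_nm = 5000, y_nm = 3000,
                           occupancy = 1, n_localizations = 1000L,
                           positions = list(pos))
  dr <- estimate_drift(tracks, 1000L)
  expect_equal(dr$dx_nm, (0:999) / 100, tolerance = 1e-12)
  expect_equal(dr$dy_nm, rep(0, 1000), tolerance = 1e-12)
  expect_identical(dr$dx_nm[1], 0)
})

test_that("noiseless fiducials pin a planted random walk to machine precision", {
  sim <- sim_drifted(54, loc_precision = 0, n_particles = 50)
  tab <- channel_table(sim)
  # wide capture radius: the walk spreads each fiducial's pooled cluster
  tr <- suppressWarnings(detect_fiducials(tab, 250, 0.999))
  expect_gte(nrow(tr), 3L)
  dr <- estimate_drift(tr, n_frames(tab))
  expect_equal(dr$dx_nm, sim$truth$drift$dx_nm, tolerance = 1e-9)
  expect_equal(dr$dy_nm, sim$truth$drift$dy_nm, tolerance = 1e-9)
})

test_that("zero planted drift estimates to zero without noise", {
  sim <- sim_drifted(55, drift_model = "none", loc_precision = 0,
                     n_particles = 50)
  tr <- suppressWarnings(detect_fiducials(channel_table(sim), 100, 0.9))
  dr <- estimate_drift(tr, 15000L)
  expect_equal(max(abs(dr$dx_nm)), 0, tolerance = 1e-9)
  expect_equal(max(abs(dr$dy_nm)), 0, tolerance = 1e-9)
})

test_that("drift subtraction shifts coordinates and nothing else", {
  sim <- sim_drifted(56, drift_model = "none", n_fiducials = 0,
                     n_particles = 30)
  tab <- channel_table(sim)
  zero <- tibble::tibble(frame = 0:14999, dx_nm = 0, dy_nm = 0)
  expect_equal(apply_drift_correction(tab, zero)$x_nm, tab$x_nm)

  const <- tibble::tibble(frame = 0:14999,
                          dx_nm = c(0, rep(10, 14999)),
                          dy_nm = c(0, rep(-5, 14999)))
  out <- apply_drift_correction(tab, const)
  late <- tab$frame >= 1
  expect_equal(out$x_nm[late], tab$x_nm[late] - 10)
  expect_equal(out$y_nm[late], tab$y_nm[late] + 5)
  expect_equal(out$frame, tab$frame)

  short <- tibble::tibble(frame = 0:99, dx_nm = 0, dy_nm = 0)
  expect_error(apply_drift_correction(tab, short),
               class = "nanocoloc_error_range")
})

test_that("correction tightens fiducial tracks and re-estimates to the noise floor", {
  sim <- sim_drifted(57)
  tab <- channel_table(sim)
  tr <- suppressWarnings(detect_fiducials(tab, 100, 0.8))
  dr <- estimate_drift(tr, n_frames(tab), smoothing_window = 51)
  corrected <- apply_drift_correction(tab, dr)

  spread <- function(t) {
    trk <- suppressWarnings(detect_fiducials(t, 100, 0.8))
    mean(vapply(trk$positions, function(p) sd(p$x_nm) + sd(p$y_nm),
                double(1)))
  }
  expect_lte(spread(corrected), spread(tab))

  tr2 <- suppressWarnings(detect_fiducials(corrected, 100, 0.8))
  dr2 <- estimate_drift(tr2, n_frames(tab), smoothing_window = 51)
  noise_floor <- 10 / sqrt(3)
  expect_lt(max(abs(dr2$dx_nm)), noise_floor)
  expect_lt(max(abs(dr2$dy_nm)), noise_floor)
})

test_that("correction does not blur the rendered fiducial peak", {
  sim <- sim_drifted(58, drift_model = "linear", drift_rate = c(0.01, -0.005),
                     n_particles = 50)
  tab <- channel_table(sim)
  tr <- suppressWarnings(detect_fiducials(tab, 150, 0.8))
  dr <- estimate_drift(tr, n_frames(tab), smoothing_window = 51)
  corrected <- apply_drift_correction(tab, dr)
  peak_near <- function(t, x, y) {
    ext <- c(xmin = x - 500, xmax = x + 500, ymin = y - 500, ymax = y + 500)
    sub <- t[abs(t$x_nm - x) < 450 & abs(t$y_nm - y) < 450, ]
    max(render_image(sub, "ch1", 10, 50, ext)$pixels)
  }
  f <- sim$truth$fiducials
  before <- peak_near(tab, f$x_nm[1], f$y_nm[1])
  after <- peak_near(corrected, f$x_nm[1], f$y_nm[1])
  expect_gte(after, before)
})

test_that("fiducial regions are excised with ground-truth completeness", {
  sim <- sim_drifted(59, drift_model = "none", n_fiducials = 2,
                     n_particles = 300)
  tab <- channel_table(sim, "ch1")
  truth_src <- sim$truth$events$source[sim$truth$events$channel == "ch1"]
  tr <- suppressWarnings(detect_fiducials(tab, 100, 0.8))
  expect_equal(nrow(tr), 2L)
  kept <- exclude_fiducial_regions(tab, tr, exclusion_radius = 300)
  removed_idx <- !seq_len(nrow(tab)) %in%
    which(paste(tab$frame, tab$x_nm) %in% paste(kept$frame, kept$x_nm))
  # every fiducial-generated event is gone
  expect_equal(sum(truth_src == "fiducial" & !removed_idx), 0L)
  expect_equal(attr(kept, "n_removed"), nrow(tab) - nrow(kept))
  # molecular events well away from fiducials are retained
  far <- truth_src == "particle" &
    sqrt((tab$x_nm - tr$x_nm[1])^2 + (tab$y_nm - tr$y_nm[1])^2) > 400 &
    sqrt((tab$x_nm - tr$x_nm[2])^2 + (tab$y_nm - tr$y_nm[2])^2) > 400
  expect_equal(sum(far), sum(paste(tab$frame[far], tab$x_nm[far]) %in%
                               paste(kept$frame, kept$x_nm)))

  # boundary containment: an event exactly at a track centre is removed
  probe <- tibble::tibble(frame = 0L, channel = "ch1",
                          x_nm = tr$x_nm[1], y_nm = tr$y_nm[1])
  expect_equal(nrow(exclude_fiducial_regions(probe, tr, 150)), 0L)
  # no tracks: unchanged
  no_tracks <- detect_fiducials(probe[0, ], 100, 0.5)
  expect_equal(nrow(exclude_fiducial_regions(tab, no_tracks, 150)),
               nrow(tab))
})

test_that("drift estimation without tracks aborts with guidance", {
  empty <- tibble::tibble(id = integer(), x_nm = double(), y_nm = double(),
                          occupancy = double(), n_localizations = integer(),
                          positions = list())
  err <- expect_error(estimate_drift(empty, 100L),
                      class = "nanocoloc_error_no_tracks")
  expect_match(conditionMessage(err), "[Ss]kip")
})
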