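# Fiducial detection, drift estimation/correction, fiducial excision.
#
# Fiducial markers (e.g. 40 nm fluorescent nanodiamonds) do not blink:
# they produce a localization in (nearly) every recorded frame at a fixed
# position, while genuine single molecules are ON in a tiny fraction of
# frames. Persistence is therefore the detection criterion.

#' Detect persistent fiducial emitters in a localization table
#'
#' Pools all frames, clusters localizations spatially (grid hash at the
#' capture radius followed by centroid refinement), and keeps clusters
#' whose occupancy — the fraction of expected frames containing at least
#' one member — reaches `min_occupancy`. For keyframe-sampled fiducials
#' (e.g. selective excitation every 1000 frames) set
#' `keyframe_interval`, and occupancy is computed over keyframes only.
#'
#' @param table Localization tibble (subset to one channel beforehand,
#'   or pass `channel`).
#' @param capture_radius Clustering linkage distance in nm (default 100).
#' @param min_occupancy Minimum occupied-frame fraction (default 0.5;
#'   blinking duty cycles are far below this).
#' @param channel Optional channel label to restrict to.
#' @param keyframe_interval Frames between fiducial observations
#'   (default 1: every frame).
#' @param n_total_frames Total frames of the acquisition; defaults to
#'   [n_frames()] of `table`.
#' @return Tibble with one row per fiducial track: `id`, `x_nm`, `y_nm`
#'   (mean position), `occupancy`, `n_localizations`, and a `positions`
#'   list-column of per-frame centroid tibbles (`frame`, `x_nm`,
#'   `y_nm`). Empty tibble when nothing passes.
#' @export
detect_fiducials <- function(table, capture_radius = 100,
                             min_occupancy = 0.5, channel = NULL,
                             keyframe_interval = 1L,
                             n_total_frames = NULL) {
  stopifnot(capture_radius > 0, min_occupancy > 0, min_occupancy <= 1)
  n_total_frames <- n_total_frames %||% n_frames(table)
  if (!is.null(channel)) {
    table <- table[table$channel == channel, , drop = FALSE]
  }
  empty <- tibble(id = integer(), x_nm = double(), y_nm = double(),
                  occupancy = double(), n_localizations = integer(),
                  positions = list())
  if (nrow(table) == 0L || n_total_frames == 0L) return(empty)

  expected_frames <- seq.int(0L, n_total_frames - 1L, by = keyframe_interval)
  n_expected <- length(expected_frames)
  min_count <- min_occupancy * n_expected

  # grid hash: candidate peaks are 3x3 cell neighbourhoods holding enough
  # events to possibly reach the occupancy threshold
  cx <- floor(table$x_nm / capture_radius)
  cy <- floor(table$y_nm / capture_radius)
  key <- paste(cx, cy)
  counts <- table(key)
  cells <- do.call(rbind, strsplit(names(counts), " "))
  cells <- data.frame(cx = as.numeric(cells[, 1]),
                      cy = as.numeric(cells[, 2]),
                      n = as.integer(counts))
  # neighbourhood sums by hashed lookup of the 8 shifted cell keys
  neigh_sum <- cells$n
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    hit <- match(paste(cells$cx + dx, cells$cy + dy), names(counts))
    neigh_sum <- neigh_sum + ifelse(is.na(hit), 0L, cells$n[hit])
  }
  cand <- cells[neigh_sum >= min_count, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  # initial centres: centroid of each candidate 3x3 neighbourhood,
  # deduplicated within the capture radius (densest first)
  cand <- cand[order(-neigh_sum[neigh_sum >= min_count]), , drop = FALSE]
  centers <- list()
  for (i in seq_len(nrow(cand))) {
    inb <- abs(cx - cand$cx[i]) <= 1 & abs(cy - cand$cy[i]) <= 1
    ctr <- c(mean(table$x_nm[inb]), mean(table$y_nm[inb]))
    dup <- any(vapply(centers, function(p)
      sum((p - ctr)^2) < capture_radius^2, logical(1)))
    if (!dup) centers[[length(centers) + 1L]] <- ctr
  }

  tracks <- list()
  id <- 0L
  for (ctr in centers) {
    # two centroid refinement passes
    for (k in 1:2) {
      inr <- (table$x_nm - ctr[1])^2 + (table$y_nm - ctr[2])^2 <=
        capture_radius^2
      if (!any(inr)) break
      ctr <- c(mean(table$x_nm[inr]), mean(table$y_nm[inr]))
    }
    if (!any(inr)) next
    members <- table[inr, , drop = FALSE]
    frames_present <- intersect(unique(members$frame), expected_frames)
    occupancy <- length(frames_present) / n_expected
    if (occupancy < min_occupancy) next
    pos <- dplyr::summarise(dplyr::group_by(members, .data$frame),
                            x_nm = mean(.data$x_nm),
                            y_nm = mean(.data$y_nm), .groups = "drop")
    pos <- dplyr::arrange(pos, .data$frame)
    id <- id + 1L
    tracks[[id]] <- tibble(id = id, x_nm = ctr[1], y_nm = ctr[2],
                           occupancy = occupancy,
                           n_localizations = nrow(members),
                           positions = list(pos))
  }
  if (length(tracks) == 0L) return(empty)
  out <- dplyr::bind_rows(tracks)
  if (any(out$n_localizations > 0.2 * nrow(table))) {
    nc_warn(paste0("A single cluster captured more than 20% of all ",
                   "localizations; capture_radius is likely too large."),
            "pathological_clustering")
  }
  out
}

#' Estimate the per-frame drift trajectory from fiducial tracks
#'
#' For each track the displacement relative to its frame-0 position is
#' linearly interpolated to every frame (keyframe-sampled tracks become
#' piecewise linear; frames outside a track's span hold the nearest
#' value, with a warning). The drift is the mean displacement over
#' tracks, optionally smoothed with a centred moving average, and
#' anchored so `dx[0] = dy[0] = 0`.
#'
#' @param tracks Fiducial tracks from [detect_fiducials()].
#' @param n_frames Total frame count.
#' @param smoothing_window Moving-average window in frames (0 = none).
#' @return A `drift_trajectory` tibble: `frame` (0-based), `dx_nm`,
#'   `dy_nm`.
#' @export
estimate_drift <- function(tracks, n_frames, smoothing_window = 0L) {
  if (nrow(tracks) == 0L) {
    nc_abort(paste0("No fiducial tracks: cannot estimate drift. ",
                    "Skip drift correction for this dataset."),
             "no_tracks")
  }
  frames <- seq.int(0L, n_frames - 1L)
  spans <- vapply(tracks$positions, function(p) range(p$frame), double(2))
  if (min(spans[1, ]) > 0L || max(spans[2, ]) < n_frames - 1L) {
    nc_warn("Frames outside all fiducial spans: drift held at the nearest value.",
            "extrapolation")
  }
  disp <- lapply(tracks$positions, function(p) {
    dx <- approx(p$frame, p$x_nm - p$x_nm[1], xout = frames, rule = 2)$y
    dy <- approx(p$frame, p$y_nm - p$y_nm[1], xout = frames, rule = 2)$y
    cbind(dx, dy)
  })
  dx <- rowMeans(vapply(disp, function(d) d[, 1], double(length(frames))))
  dy <- rowMeans(vapply(disp, function(d) d[, 2], double(length(frames))))
  if (smoothing_window > 1L) {
    dx <- run_mean(dx, smoothing_window)
    dy <- run_mean(dy, smoothing_window)
  }
  out <- tibble(frame = frames, dx_nm = dx - dx[1], dy_nm = dy - dy[1])
  class(out) <- c("drift_trajectory", class(out))
  out
}

#' Subtract the estimated drift from localization coordinates
#'
#' Each event's position becomes `(x - dx[frame], y - dy[frame])`; all
#' other fields are untouched.
#'
#' @param table Localization tibble.
#' @param drift A `drift_trajectory` covering every frame in `table`.
#' @return Corrected localization tibble (attributes preserved).
#' @export
apply_drift_correction <- function(table, drift) {
  if (nrow(table) == 0L) return(table)
  idx <- match(table$frame, drift$frame)
  if (anyNA(idx)) {
    nc_abort("Drift trajectory does not cover all frames in the table.",
             "range")
  }
  out <- table
  out$x_nm <- table$x_nm - drift$dx_nm[idx]
  out$y_nm <- table$y_nm - drift$dy_nm[idx]
  out
}

#' Remove localizations around fiducial positions
#'
#' Fiducial markers are bright, persistent, and not molecules: their
#' events must not enter the colocalization analysis. Every localization
#' within `exclusion_radius` of any track's mean position is removed.
#'
#' @param table Localization tibble.
#' @param tracks Fiducial tracks from [detect_fiducials()].
#' @param exclusion_radius Radius in nm (default 150, comfortably above
#'   a 40 nm fiducial plus the rendering width).
#' @return Filtered tibble; the number of removed events is in the
#'   `n_removed` attribute.
#' @export
exclude_fiducial_regions <- function(table, tracks, exclusion_radius = 150) {
  stopifnot(exclusion_radius > 0)
  if (nrow(tracks) == 0L || nrow(table) == 0L) {
    attr(table, "n_removed") <- 0L
    return(table)
  }
  drop <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(tracks))) {
    drop <- drop | ((table$x_nm - tracks$x_nm[i])^2 +
                      (table$y_nm - tracks$y_nm[i])^2 <= exclusion_radius^2)
  }
  out <- table[!drop, , drop = FALSE]
  attr(out, "n_frames") <- attr(table, "n_frames", exact = TRUE)
  attr(out, "n_removed") <- sum(drop)
  out
}

#' @describeIn estimate_drift Line plot of the drift trajectory.
#' @param object,... `autoplot` arguments.
#' @export
autoplot.drift_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("dx_nm", "dy_nm"),
                            names_to = "axis", values_to = "drift_nm")
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$drift_nm,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "drift (nm)", colour = NULL,
                  title = "Estimated stage drift")
}
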