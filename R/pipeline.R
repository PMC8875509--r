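# End-to-end orchestration: acquire -> drift-correct -> excise fiducials
# -> render -> global ICCS -> local map (-> mask-restricted ICCS), with a
# JSON report carrying every parameter for reproducibility.

#' Assemble a pipeline configuration
#'
#' All parameters of every stage with their defaults; any subset can be
#' overridden. `input` is either `list(kind = "simulate", preset =
#' "positive"|"negative"|"custom", n_cells = 1, config = sim overrides)`
#' or `list(kind = "file", path = <csv>, dialect = loc_dialect())`.
#'
#' @param input Input description (see above).
#' @param seed Integer master seed; cell i of a simulated input uses
#'   `seed + i - 1`.
#' @param channels Two channel labels (default `c("ch1", "ch2")`).
#' @param drift Drift-stage parameters: `enabled`, `capture_radius`,
#'   `min_occupancy`, `keyframe_interval`, `smoothing_window`,
#'   `exclusion_radius`.
#' @param render Rendering parameters: `pixel_size` (10 nm),
#'   `psf_width` (50 nm).
#' @param iccs Correlation parameters: `max_lag` (32), `fit_radius`.
#' @param local Local-map parameters: `enabled`, `window` (69), `step`.
#' @param mask Optional mask stage: either a logical matrix /
#'   `nc_mask` on the rendered grid, or `list(confocal = <path or
#'   confocal_image>, pixel_size, min_area, src_points, dst_points,
#'   model)` to segment + register.
#' @param output_dir Directory for report files; `NULL` = don't write.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = list(kind = "simulate",
                                         preset = "positive",
                                         n_cells = 1),
                            seed = 1L,
                            channels = c("ch1", "ch2"),
                            drift = list(),
                            render = list(),
                            iccs = list(),
                            local = list(),
                            mask = NULL,
                            output_dir = NULL) {
  structure(list(
    input = input, seed = as.integer(seed), channels = channels,
    drift = modifyList(list(enabled = TRUE, capture_radius = 100,
                            min_occupancy = 0.5, keyframe_interval = 1000L,
                            smoothing_window = 0L, exclusion_radius = 150),
                       drift),
    render = modifyList(list(pixel_size = 10, psf_width = 50), render),
    iccs = modifyList(list(max_lag = 32, fit_radius = NULL), iccs),
    local = modifyList(list(enabled = TRUE, window = 69, step = NULL), local),
    mask = mask,
    output_dir = output_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

acquire_cell <- function(cfg, cell) {
  inp <- cfg$input
  if (identical(inp$kind, "file")) {
    tab <- read_localizations(inp$path,
                              dialect = inp$dialect %||% loc_dialect())
    return(list(table = tab, truth = NULL))
  }
  seed <- cfg$seed + cell - 1L
  overrides <- modifyList(inp$config %||% list(), list(seed = seed))
  sim <- if (identical(inp$preset, "custom")) {
    do.call(sim_config, overrides)
  } else {
    do.call(sim_preset, c(list(preset = inp$preset %||% "positive"),
                          overrides))
  }
  simulate_dataset(sim)
}

run_cell <- function(cfg, cell) {
  acq <- acquire_cell(cfg, cell)
  tab <- acq$table
  stage_log("acquire", sprintf("cell %d: %d localizations, %d frames",
                               cell, nrow(tab), n_frames(tab)))

  drift_est <- NULL
  n_excluded <- 0L
  if (isTRUE(cfg$drift$enabled)) {
    all_tracks <- list()
    for (ch in cfg$channels) {
      tr <- detect_fiducials(tab, capture_radius = cfg$drift$capture_radius,
                             min_occupancy = cfg$drift$min_occupancy,
                             channel = ch,
                             keyframe_interval = cfg$drift$keyframe_interval)
      if (nrow(tr) > 0L) {
        # per-channel estimation; correction applied to that channel
        dr <- estimate_drift(tr, n_frames(tab),
                             smoothing_window = cfg$drift$smoothing_window)
        sel <- tab$channel == ch
        sub <- tab[sel, , drop = FALSE]
        attr(sub, "n_frames") <- n_frames(tab)
        tab[sel, c("x_nm", "y_nm")] <-
          apply_drift_correction(sub, dr)[, c("x_nm", "y_nm")]
        drift_est <- dr
        all_tracks[[ch]] <- tr
      }
    }
    tracks <- dplyr::bind_rows(all_tracks)
    if (nrow(tracks) > 0L) {
      tab <- exclude_fiducial_regions(tab, tracks,
                                      cfg$drift$exclusion_radius)
      n_excluded <- attr(tab, "n_removed")
      stage_log("drift", sprintf(
        "cell %d: %d fiducial track(s), %d events excised",
        cell, nrow(tracks), n_excluded))
    } else {
      stage_log("drift", sprintf("cell %d: no fiducials found, skipping", cell))
    }
  }

  ext <- default_extent(tab, cfg$render$psf_width)
  imgs <- lapply(cfg$channels, function(ch)
    render_image(tab, ch, pixel_size = cfg$render$pixel_size,
                 psf_width = cfg$render$psf_width, extent = ext))
  stage_log("render", sprintf("cell %d: %d x %d px grid", cell,
                              nrow(imgs[[1]]$pixels), ncol(imgs[[1]]$pixels)))

  res <- compute_iccs(imgs[[1]], imgs[[2]],
                      max_lag = cfg$iccs$max_lag,
                      fit_radius = cfg$iccs$fit_radius)
  stage_log("iccs", sprintf("cell %d: f_ICCS = %.3f, d = %.1f nm", cell,
                            res$f_iccs, res$d_nm %||% NA_real_))

  lmap <- NULL
  if (isTRUE(cfg$local$enabled) &&
      min(dim(imgs[[1]]$pixels)) >= cfg$local$window) {
    lmap <- local_iccs(imgs[[1]], imgs[[2]], window = cfg$local$window,
                       step = cfg$local$step, max_lag = cfg$iccs$max_lag)
    stage_log("localmap", sprintf("cell %d: %d valid cells", cell,
                                  sum(lmap$valid)))
  }

  masked <- NULL
  if (!is.null(cfg$mask)) {
    mk <- cfg$mask
    if (is.list(mk) && !inherits(mk, "nc_mask") && !is.matrix(mk)) {
      conf <- if (is.character(mk$confocal)) {
        read_grayscale_image(mk$confocal, mk$pixel_size %||% 70)
      } else mk$confocal
      seg <- segment_foci(conf, min_area = mk$min_area %||% 20)
      tf <- estimate_transform(mk$src_points, mk$dst_points,
                               model = mk$model %||% "similarity")
      mk <- transfer_mask(seg, tf, imgs[[1]])
    }
    masked <- masked_iccs(imgs[[1]], imgs[[2]], mk,
                          max_lag = cfg$iccs$max_lag,
                          fit_radius = cfg$iccs$fit_radius)
    stage_log("mask", sprintf("cell %d: masked f_ICCS = %.3f (coverage %.1f%%)",
                              cell, masked$f_iccs, 100 * masked$mask_coverage))
  }

  list(table = tab, images = imgs, iccs = res, local = lmap,
       masked = masked, drift = drift_est, n_excluded = n_excluded,
       truth = acq$truth)
}

#' Run the full analysis pipeline
#'
#' Executes, per cell: acquisition (simulation preset or file), fiducial
#' detection + drift correction + fiducial excision, dual-channel
#' Gaussian rendering on a shared grid, global ICCS, local
#' colocalization map, and (when configured) mask-restricted ICCS. The
#' summary reports mean and SD of `f_ICCS` and `d` across cells and
#' embeds the complete parameter set. With `output_dir` set, writes
#' `summary.json`, per-cell drift trajectories and radial profiles
#' (CSV), and `f`/`d` maps (TIFF).
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return The report: `summary` (list, what `summary.json` contains)
#'   and `cells` (per-cell stage outputs), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  n_cells <- if (identical(config$input$kind, "file")) 1L
             else as.integer(config$input$n_cells %||% 1L)

  cells <- lapply(seq_len(n_cells), function(i) {
    tryCatch(run_cell(config, i), nanocoloc_error = function(e) {
      nc_abort(paste0("Pipeline failed at cell ", i, ": ",
                      conditionMessage(e),
                      " Check the stage parameters against the input."),
               "pipeline")
    })
  })

  f_vals <- vapply(cells, function(cl) cl$iccs$f_iccs, double(1))
  d_vals <- vapply(cells, function(cl) cl$iccs$d_nm %||% NA_real_, double(1))
  summary <- list(
    n_cells = n_cells,
    f_iccs = list(mean = mean(f_vals), sd = if (n_cells > 1) sd(f_vals) else NA,
                  per_cell = f_vals),
    d_nm = list(mean = mean(d_vals, na.rm = TRUE),
                sd = if (n_cells > 1) sd(d_vals) else NA,
                per_cell = d_vals),
    masked_f_iccs = if (!is.null(cells[[1]]$masked)) {
      mv <- vapply(cells, function(cl) cl$masked$f_iccs, double(1))
      list(mean = mean(mv), sd = if (n_cells > 1) sd(mv) else NA,
           per_cell = mv)
    },
    fits = lapply(cells[[1]]$iccs$fits, function(f)
      list(g0 = f$g0, w_nm = f$w_nm, g_inf = f$g_inf,
           converged = f$converged)),
    n_fiducial_events_excluded = vapply(cells, function(cl)
      as.integer(cl$n_excluded %||% 0L), integer(1)),
    parameters = config[c("input", "seed", "channels", "drift", "render",
                          "iccs", "local")]
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    for (i in seq_len(n_cells)) {
      cl <- cells[[i]]
      prof <- dplyr::bind_rows(lapply(names(cl$iccs$surfaces), function(k) {
        p <- radial_profile(cl$iccs$surfaces[[k]]); p$component <- k; p
      }))
      readr::write_csv(prof, file.path(config$output_dir,
                                       sprintf("cell%02d_radial_profiles.csv", i)))
      if (!is.null(cl$drift)) {
        readr::write_csv(as_tibble(cl$drift),
                         file.path(config$output_dir,
                                   sprintf("cell%02d_drift.csv", i)))
      }
      if (!is.null(cl$local)) {
        fm <- cl$local$f_map; fm[!cl$local$valid] <- 0
        dm <- cl$local$d_map; dm[!cl$local$valid | is.na(cl$local$d_map)] <- 0
        write_image_tiff(fm, file.path(config$output_dir,
                                       sprintf("cell%02d_f_map.tif", i)))
        write_image_tiff(dm, file.path(config$output_dir,
                                       sprintf("cell%02d_d_map.tif", i)))
      }
    }
    stage_log("report", paste0("written to ", config$output_dir))
  }
  invisible(list(summary = summary, cells = cells))
}
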