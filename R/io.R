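#' Column-mapping dialect for localization files
#'
#' Describes how a delimited localization file maps onto the native schema
#' (`frame`, `channel`, `x_nm`, `y_nm`, `photons`, `precision_nm`). The
#' native dialect is comma-separated with exactly those column names,
#' coordinates in nm and 0-based frames. Vendor exports with other headers
#' (e.g. `"x [nm]"`), camera-pixel units or 1-based frame counters are
#' accommodated by overriding fields here.
#'
#' @param frame,x,y,channel,photons,precision Column names in the file.
#'   `channel`, `photons` and `precision` may be `NA` (absent).
#' @param units Either `"nm"` or `"px"`; with `"px"`, `pixel_size_nm`
#'   must be given and coordinates are multiplied by it on read.
#' @param pixel_size_nm Camera pixel size in nm (required for `units = "px"`).
#' @param frame_base 0 or 1; 1-based frame counters are shifted to 0-based.
#' @param delim Field delimiter.
#' @return A `loc_dialect` list.
#' @examples
#' loc_dialect(x = "x [nm]", y = "y [nm]", frame = "frame")
#' @export
loc_dialect <- function(frame = "frame", x = "x_nm", y = "y_nm",
                        channel = "channel", photons = "photons",
                        precision = "precision_nm",
                        units = c("nm", "px"), pixel_size_nm = NULL,
                        frame_base = 0L, delim = ",") {
  units <- match.arg(units)
  if (units == "px" && !is_scalar_number(pixel_size_nm)) {
    nc_abort("`pixel_size_nm` must be given when coordinates are in camera pixels.",
             "config")
  }
  if (!frame_base %in% c(0L, 1L)) {
    nc_abort("`frame_base` must be 0 or 1.", "config")
  }
  structure(
    list(frame = frame, x = x, y = y, channel = channel,
         photons = photons, precision = precision,
         units = units, pixel_size_nm = pixel_size_nm,
         frame_base = as.integer(frame_base), delim = delim),
    class = "loc_dialect"
  )
}

#' Read a single-molecule localization table
#'
#' Parses a delimited text file of localization events into a tibble with
#' the native columns `frame` (integer, 0-based), `channel` (character),
#' `x_nm`, `y_nm` and, when present in the file, `photons` and
#' `precision_nm`. Unit conversion to nm and frame re-basing are applied
#' according to `dialect`.
#'
#' @param path Path to the file.
#' @param dialect A [loc_dialect()] describing the file's columns and units.
#' @param n_frames Total frame count of the acquisition; defaults to
#'   `max(frame) + 1`. Stored as the `n_frames` attribute.
#' @param on_malformed `"error"` (default): abort on rows with non-numeric
#'   or non-finite coordinates, reporting line numbers; `"drop"`: remove
#'   them with a warning and record the count in the `n_malformed`
#'   attribute.
#' @return A tibble of localizations with attributes `n_frames` and
#'   `n_malformed`.
#' @export
read_localizations <- function(path, dialect = loc_dialect(),
                               n_frames = NULL,
                               on_malformed = c("error", "drop")) {
  on_malformed <- match.arg(on_malformed)
  if (!file.exists(path)) {
    nc_abort(paste0("Localization file not found: ", path), "io")
  }
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    if (length(names(raw)) == 0L) {
      nc_abort(paste0("Empty localization file: ", path), "empty_input")
    }
    # header-only file: legal empty table, but required columns must exist
  }
  required <- c(frame = dialect$frame, x = dialect$x, y = dialect$y)
  missing <- required[!required %in% names(raw)]
  if (length(missing) > 0L) {
    nc_abort(paste0("Required column(s) missing from ", path, ": ",
                    paste0("'", missing, "'", collapse = ", ")),
             "missing_column")
  }
  if (nrow(raw) == 0L) {
    out <- tibble(frame = integer(), channel = character(),
                  x_nm = double(), y_nm = double())
    attr(out, "n_frames") <- as.integer(n_frames %||% 0L)
    attr(out, "n_malformed") <- 0L
    return(out)
  }

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  frame <- suppressWarnings(as.integer(round(num(dialect$frame))))
  x <- num(dialect$x)
  y <- num(dialect$y)
  bad <- !is.finite(frame) | !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for header line
    if (on_malformed == "error") {
      nc_abort(paste0("Non-numeric or non-finite coordinates at line(s): ",
                      paste(head(lines, 10L), collapse = ", "),
                      if (length(lines) > 10L) " ..."),
               "malformed_row")
    }
    nc_warn(paste0("Dropped ", length(lines), " malformed row(s)."),
            "malformed_row")
  }
  scale <- if (dialect$units == "px") dialect$pixel_size_nm else 1
  out <- tibble(
    frame = frame - dialect$frame_base,
    channel = if (!is.na(dialect$channel) && dialect$channel %in% names(raw))
      as.character(raw[[dialect$channel]]) else "ch1",
    x_nm = x * scale,
    y_nm = y * scale
  )
  if (!is.na(dialect$photons) && dialect$photons %in% names(raw)) {
    out$photons <- num(dialect$photons)
  }
  if (!is.na(dialect$precision) && dialect$precision %in% names(raw)) {
    out$precision_nm <- num(dialect$precision) * scale
  }
  out <- out[!bad, , drop = FALSE]
  validate_localizations(out, n_frames = n_frames)
  attr(out, "n_frames") <- as.integer(n_frames %||% (max(out$frame) + 1L))
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Validate a localization table
#'
#' Checks the table invariants: finite coordinates, non-negative frames
#' within `[0, n_frames)`, positive photon counts and precisions when
#' present.
#'
#' @param table Localization tibble.
#' @param n_frames Optional declared frame count to check frames against.
#' @return `table`, invisibly. Aborts on violation.
#' @export
validate_localizations <- function(table, n_frames = NULL) {
  need <- c("frame", "channel", "x_nm", "y_nm")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) {
    nc_abort(paste0("Localization table lacks column(s): ",
                    paste(miss, collapse = ", ")), "missing_column")
  }
  if (nrow(table) == 0L) return(invisible(table))
  if (!all(is.finite(table$x_nm)) || !all(is.finite(table$y_nm))) {
    nc_abort("Non-finite coordinates in localization table.", "invalid_value")
  }
  if (any(table$frame < 0L)) {
    nc_abort("Negative frame indices (frames are 0-based).", "invalid_value")
  }
  if (!is.null(n_frames) && any(table$frame >= n_frames)) {
    nc_abort(paste0("Frame indices exceed declared n_frames = ", n_frames, "."),
             "invalid_value")
  }
  if ("photons" %in% names(table) &&
      any(table$photons <= 0, na.rm = TRUE)) {
    nc_abort("Photon counts must be positive.", "invalid_value")
  }
  if ("precision_nm" %in% names(table) &&
      any(table$precision_nm <= 0, na.rm = TRUE)) {
    nc_abort("Localization precisions must be positive.", "invalid_value")
  }
  invisible(table)
}

#' Write a localization table in the native dialect
#'
#' Comma-separated with header `frame,channel,x_nm,y_nm[,photons]
#' [,precision_nm]`. Values round-trip through [read_localizations()]
#' to well below 1e-6 nm.
#'
#' @param table Localization tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  validate_localizations(table)
  keep <- intersect(c("frame", "channel", "x_nm", "y_nm",
                      "photons", "precision_nm"), names(table))
  readr::write_csv(table[keep], path, progress = FALSE)
  invisible(path)
}

#' Read a single-plane grayscale image (TIFF)
#'
#' @param path TIFF path (single plane, single channel).
#' @param pixel_size Physical pixel size in nm/pixel.
#' @param origin Physical (x0, y0) in nm of the top-left pixel corner.
#' @return A `confocal_image` object (`pixels` matrix, `pixel_size`,
#'   `origin`).
#' @export
read_grayscale_image <- function(path, pixel_size, origin = c(0, 0)) {
  if (!file.exists(path)) nc_abort(paste0("Image not found: ", path), "io")
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L) {
      nc_abort("Expected a single-channel grayscale image.", "config")
    }
    px <- px[, , 1L]
  }
  new_confocal_image(px, pixel_size, origin)
}

new_confocal_image <- function(pixels, pixel_size, origin = c(0, 0)) {
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "confocal_image")
}

#' Write a pixel grid as 32-bit float TIFF
#'
#' Works for rendered images, confocal images, colocalization maps
#' (a bare matrix is also accepted). TIFF float samples are stored on a
#' `[0, 1]` scale, so grids whose maximum exceeds 1 are divided by that
#' maximum; the scale factor is returned so quantitative values can be
#' recovered (the pipeline also writes the raw values as CSV).
#'
#' @param image Object with a `pixels` matrix, or a matrix.
#' @param path Output path.
#' @return The intensity scale factor (nm or counts per stored unit),
#'   invisibly.
#' @export
write_image_tiff <- function(image, path) {
  px <- if (is.matrix(image)) image else image$pixels
  storage.mode(px) <- "double"
  px[px < 0 | !is.finite(px)] <- 0
  scale <- max(px, 1)
  tiff::writeTIFF(px / scale, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' @export
print.confocal_image <- function(x, ...) {
  cat(sprintf("<confocal_image> %d x %d px, %.1f nm/px, origin (%.0f, %.0f) nm\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}
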