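# internal helpers shared across modules

nc_abort <- function(msg, class, ...) {
  abort(msg, class = c(paste0("nanocoloc_error_", class), "nanocoloc_error"), ...)
}

nc_warn <- function(msg, class) {
  warn(msg, class = c(paste0("nanocoloc_warning_", class), "nanocoloc_warning"))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Number of frames spanned by a localization table
#'
#' Returns the `n_frames` attribute when present (set by
#' [read_localizations()] and [simulate_dataset()]), otherwise
#' `max(frame) + 1` (frames are 0-based).
#'
#' @param table A localization table (data frame with a `frame` column).
#' @return Integer frame count.
#' @export
n_frames <- function(table) {
  nf <- attr(table, "n_frames", exact = TRUE)
  if (!is.null(nf)) return(as.integer(nf))
  if (nrow(table) == 0L) return(0L)
  as.integer(max(table$frame) + 1L)
}

# centered moving average; the window shrinks near the ends (no edge
# padding, so no single sample is overweighted at the boundaries)
run_mean <- function(x, window) {
  if (window <= 1L) return(x)
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
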