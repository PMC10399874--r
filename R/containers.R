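#' Photon-count image time-stack
#'
#' Container for an N&B acquisition: an integer photon-count array of
#' dimension frames x height x width plus the acquisition metadata needed by
#' the moment analysis.
#'
#' @param counts integer array, frames x height x width, non-negative counts.
#' @param pixel_dwell_time pixel dwell time in seconds (> 0).
#' @param pixel_size pixel edge length in micrometres.
#' @param frame_interval time between frame starts in seconds.
#' @param laser_power_label free-text metadata (e.g. "1.2 uW").
#' @param config optional [sim_config()] that generated the stack.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(counts, pixel_dwell_time, pixel_size,
                        frame_interval, laser_power_label = "",
                        config = NULL) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3L)
    stop("counts must be a frames x height x width array")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.numeric(pixel_dwell_time) || pixel_dwell_time <= 0)
    stop("pixel_dwell_time must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(list(counts = counts,
                 pixel_dwell_time = pixel_dwell_time,
                 pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 laser_power_label = laser_power_label,
                 config = config),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<image_stack> %d frames of %d x %d px, dwell %.3g us, frame interval %.3g s\n",
              d[1], d[2], d[3], x$pixel_dwell_time * 1e6, x$frame_interval))
  cat(sprintf("  mean %.3f counts/px/frame, max %d\n",
              mean(x$counts), max(x$counts)))
  invisible(x)
}

#' Line-scan kymograph
#'
#' Repeated line scans across a membrane: a lines x pixels count matrix with
#' the line scan time and pixel size.
#'
#' @param counts integer matrix, lines x pixels, non-negative.
#' @param line_time time per line in seconds (> 0).
#' @param pixel_size pixel size in micrometres.
#' @param config optional generating [sim_config()].
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(counts, line_time, pixel_size, config = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.numeric(line_time) || line_time <= 0) stop("line_time must be > 0")
  structure(list(counts = counts, line_time = line_time,
                 pixel_size = pixel_size, config = config),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d lines x %d px, line time %.4g us\n",
              nrow(x$counts), ncol(x$counts), x$line_time * 1e6))
  invisible(x)
}

#' Intensity time trace
#'
#' A photon-count (or background-subtracted intensity) time series with a
#' fixed bin width.
#'
#' @param counts numeric vector of length >= 2, non-negative.
#' @param dt bin width in seconds (> 0).
#' @param config optional generating [sim_config()].
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(counts, dt, config = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("trace must have length >= 2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(counts = counts, dt = dt, config = config),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d bins of %.4g us, mean rate %.4g counts/s\n",
              length(x$counts), x$dt * 1e6, mean(x$counts) / x$dt))
  invisible(x)
}

#' Autocorrelation curve
#'
#' Lag times with autocorrelation amplitudes `G` and optional per-lag
#' standard deviation from segment averaging.
#'
#' @param lags lag times in seconds, strictly increasing.
#' @param G autocorrelation amplitudes.
#' @param sd_G optional per-lag standard error (from segments).
#' @param n_segments number of segments used for `sd_G`.
#' @param n_rejected number of segments flagged as intensity outliers.
#' @param dt bin width of the source trace in seconds.
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, G, sd_G = NULL, n_segments = 0L,
                              n_rejected = 0L, dt = NULL) {
  if (length(lags) != length(G)) stop("lags and G lengths differ")
  if (any(diff(lags) <= 0)) stop("lags must be strictly increasing")
  structure(list(lags = as.numeric(lags), G = as.numeric(G),
                 sd_G = sd_G, n_segments = n_segments,
                 n_rejected = n_rejected, dt = dt),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d lags, %.3g us .. %.3g s, G(first) = %.4g\n",
              length(x$lags), min(x$lags) * 1e6, max(x$lags), x$G[1]))
  invisible(x)
}
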