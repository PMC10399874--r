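#' Per-pixel temporal mean and variance
#'
#' Moment inputs of the N&B analysis: for each pixel, the temporal mean kbar
#' and the unbiased (n - 1) temporal variance of its photon counts.
#'
#' @param stack an [image_stack()] with >= 2 frames.
#' @return A list with `mean` and `variance` (height x width matrices) and
#'   `n_frames`.
#' @export
pixel_statistics <- function(stack) {
  d <- dim(stack$counts)
  nf <- d[1]
  if (nf < 2) stop("pixel statistics require at least 2 frames")
  m <- matrix(as.numeric(stack$counts), nrow = nf)
  mu <- colMeans(m)
  v <- (colSums(m * m) - nf * mu^2) / (nf - 1)
  v[v < 0] <- 0   # guard tiny negative round-off
  list(mean = matrix(mu, d[2], d[3]),
       variance = matrix(v, d[2], d[3]),
       n_frames = nf)
}

#' Photon-counting N&B brightness and number maps
#'
#' The shot-noise-subtracted moment estimators for photon-counting
#' detection: epsilon = (sigma^2 - kbar)/kbar counts per dwell per molecule
#' and n = kbar^2/(sigma^2 - kbar). Pixels with sigma^2 <= kbar (no number
#' fluctuation above shot noise) or kbar = 0 get the boundary value
#' epsilon = 0 and are flagged invalid for n; no NaN/Inf is ever emitted.
#'
#' @param mean_map,variance_map matrices from [pixel_statistics()].
#' @param dwell pixel dwell time in seconds (> 0), used to convert epsilon
#'   to counts/s/molecule.
#' @return An object of class `brightness_map`: `epsilon_cps`,
#'   `epsilon_per_dwell`, `number`, `mean_counts`, `variance`, `valid_mask`,
#'   `dwell`.
#' @export
brightness_number <- function(mean_map, variance_map, dwell) {
  if (dwell <= 0) stop("dwell must be > 0")
  excess <- variance_map - mean_map
  valid <- excess > 0 & mean_map > 0
  eps <- matrix(0, nrow(mean_map), ncol(mean_map))
  eps[valid] <- excess[valid] / mean_map[valid]
  num <- matrix(NA_real_, nrow(mean_map), ncol(mean_map))
  num[valid] <- mean_map[valid]^2 / excess[valid]
  structure(list(epsilon_cps = eps / dwell,
                 epsilon_per_dwell = eps,
                 number = num,
                 mean_counts = mean_map,
                 variance = variance_map,
                 valid_mask = valid,
                 dwell = dwell),
            class = "brightness_map")
}

#' @export
print.brightness_map <- function(x, ...) {
  cat(sprintf("<brightness_map> %d x %d px, %.1f%% valid, median epsilon %.4g counts/s/molecule\n",
              nrow(x$epsilon_cps), ncol(x$epsilon_cps),
              100 * mean(x$valid_mask),
              median(x$epsilon_cps[x$valid_mask])))
  invisible(x)
}

#' Detector-saturation mask
#'
#' Flags pixels whose maximum per-frame photon-count rate exceeds
#' `max_rate` (default 1 MHz, i.e. 50 counts per 50 us dwell); such pixels
#' are excluded from brightness analysis to avoid detector nonlinearity.
#'
#' @param stack an [image_stack()].
#' @param max_rate maximum admissible counting rate, counts/s.
#' @return Logical height x width matrix, TRUE where the pixel is masked
#'   (excluded).
#' @export
saturation_mask <- function(stack, max_rate = 1e6) {
  d <- dim(stack$counts)
  m <- matrix(stack$counts, nrow = d[1])
  mx <- do.call(pmax, c(asplit(m, 1), list(na.rm = TRUE)))
  matrix(mx / stack$pixel_dwell_time > max_rate, d[2], d[3])
}

#' Boxcar-windowed brightness with extrapolation to the start
#'
#' Partial correction for photobleaching and slow cell movement: the stack
#' is split into consecutive non-overlapping windows of `window` frames
#' (remainder frames dropped), the brightness is computed within each
#' window, and an ordinary least-squares line through the window values
#' versus window mid-times is extrapolated to the temporal midpoint of the
#' very first frame.
#'
#' In the default `pool = "roi"` mode the per-window brightness is the
#' moment-pooled estimator over the ROI, (mean over pixels of sigma^2 -
#' mean of kbar) / mean of kbar, which is far less noisy at 8-frame windows
#' than averaging per-pixel ratios. `pool = "pixel"` instead extrapolates
#' pixel-wise and returns per-pixel maps.
#'
#' @param stack an [image_stack()] with >= 2 * `window` frames.
#' @param window frames per boxcar window (default 8).
#' @param roi optional logical matrix restricting the pooled region.
#' @param sat_mask optional logical matrix of saturated pixels to exclude
#'   (see [saturation_mask()]).
#' @param pool `"roi"` (default) or `"pixel"`.
#' @return A list of class `boxcar_series`: `window_epsilon` (counts/dwell;
#'   vector, or matrix pixels x windows for `pool = "pixel"`),
#'   `window_mid_times` (s), `extrapolated_epsilon` (counts/dwell),
#'   `extrapolated_epsilon_cps`, `slope` (counts/dwell per s), `window`,
#'   `n_windows`, and `map`, the whole-stack [brightness_number()] map.
#' @export
boxcar_brightness <- function(stack, window = 8L, roi = NULL,
                              sat_mask = NULL, pool = c("roi", "pixel")) {
  pool <- match.arg(pool)
  d <- dim(stack$counts)
  nf <- d[1]; npx <- d[2] * d[3]
  nwin <- nf %/% window
  if (nwin < 2) stop("need at least 2 complete boxcar windows")
  m <- matrix(as.numeric(stack$counts), nrow = nf)
  include <- rep(TRUE, npx)
  if (!is.null(roi)) include <- include & as.vector(roi)
  if (!is.null(sat_mask)) include <- include & !as.vector(sat_mask)
  if (!any(include)) stop("no pixels left after ROI/saturation masking")
  fi <- stack$frame_interval
  frame_mid <- (seq_len(nf) - 0.5) * fi
  mid_times <- vapply(seq_len(nwin), function(w)
    mean(frame_mid[((w - 1) * window + 1):(w * window)]), numeric(1))
  t0 <- frame_mid[1]

  win_mu <- matrix(NA_real_, npx, nwin)
  win_v <- matrix(NA_real_, npx, nwin)
  for (w in seq_len(nwin)) {
    rows <- ((w - 1) * window + 1):(w * window)
    sub <- m[rows, , drop = FALSE]
    mu <- colMeans(sub)
    win_mu[, w] <- mu
    win_v[, w] <- (colSums(sub * sub) - window * mu^2) / (window - 1)
  }

  stats <- pixel_statistics(stack)
  map <- brightness_number(stats$mean, stats$variance,
                           stack$pixel_dwell_time)

  if (pool == "roi") {
    kbar <- colMeans(win_mu[include, , drop = FALSE])
    s2 <- colMeans(win_v[include, , drop = FALSE])
    eps_w <- (s2 - kbar) / kbar
    fit <- lm(eps_w ~ mid_times)
    slope <- unname(coef(fit)[2])
    eps0 <- unname(coef(fit)[1] + slope * t0)
    out <- list(window_epsilon = eps_w)
  } else {
    eps_px <- (win_v - win_mu) / win_mu   # per-pixel, per-window
    tc <- mid_times - mean(mid_times)
    slope <- as.vector(eps_px %*% tc) / sum(tc^2)
    eps0_px <- rowMeans(eps_px) + slope * (t0 - mean(mid_times))
    eps0 <- matrix(eps0_px, d[2], d[3])
    slope <- matrix(slope, d[2], d[3])
    out <- list(window_epsilon = eps_px)
  }
  structure(c(out,
              list(window_mid_times = mid_times,
                   extrapolated_epsilon = eps0,
                   extrapolated_epsilon_cps = eps0 / stack$pixel_dwell_time,
                   slope = slope,
                   window = window, n_windows = nwin,
                   extrapolation_time = t0,
                   pool = pool, map = map)),
            class = "boxcar_series")
}

#' Bleached fraction of an acquisition
#'
#' Fraction of total fluorescence signal lost between the beginning and the
#' end of a measurement: 1 - mean(last 5\% of time points) / mean(first
#' 5\%). Slightly negative values (intensity increase under noise) are
#' allowed and flagged.
#'
#' @param x an [image_stack()] (per-frame total intensities are used), an
#'   [intensity_trace()], or a numeric vector of intensities; >= 20 time
#'   points required.
#' @param edge_fraction fraction of time points averaged at each end
#'   (default 0.05).
#' @return A list: `fraction`, `head_mean`, `tail_mean`, `n_edge`,
#'   `increased` (TRUE if the fraction is negative).
#' @export
bleached_fraction <- function(x, edge_fraction = 0.05) {
  totals <- if (inherits(x, "image_stack")) {
    rowSums(matrix(x$counts, nrow = dim(x$counts)[1]))
  } else if (inherits(x, "intensity_trace")) {
    x$counts
  } else {
    as.numeric(x)
  }
  n <- length(totals)
  if (n < 20) stop("bleached_fraction requires >= 20 time points")
  k <- max(1L, floor(edge_fraction * n))
  head_mean <- mean(totals[seq_len(k)])
  tail_mean <- mean(totals[(n - k + 1):n])
  if (head_mean == 0) stop("zero initial intensity")
  fraction <- 1 - tail_mean / head_mean
  list(fraction = fraction, head_mean = head_mean, tail_mean = tail_mean,
       n_edge = k, increased = fraction < 0)
}

#' ROI-averaged brightness
#'
#' Mean molecular brightness over the valid pixels of a region of interest,
#' excluding saturated and invalid (no excess variance) pixels. This is the
#' per-cell value that feeds monomer/dimer pooling.
#'
#' @param map a [brightness_number()] map.
#' @param roi logical matrix (TRUE inside the ROI); default whole image.
#' @param sat_mask optional logical matrix of saturated pixels.
#' @return A list: `epsilon_cps`, `epsilon_per_dwell`, `number` (mean n over
#'   the same pixels), `n_pixels`.
#' @export
roi_brightness <- function(map, roi = NULL, sat_mask = NULL) {
  include <- map$valid_mask
  if (!is.null(roi)) include <- include & roi
  if (!is.null(sat_mask)) include <- include & !sat_mask
  if (!any(include)) stop("empty ROI after masking")
  list(epsilon_cps = mean(map$epsilon_cps[include]),
       epsilon_per_dwell = mean(map$epsilon_per_dwell[include]),
       number = mean(map$number[include]),
       n_pixels = sum(include))
}

#' Per-cell N&B summary
#'
#' Convenience wrapper running the full per-stack N&B pipeline: saturation
#' masking, boxcar-corrected brightness extrapolated to the start of the
#' acquisition, and the bleached fraction.
#'
#' @param stack an [image_stack()].
#' @param window boxcar window in frames.
#' @param max_rate saturation threshold, counts/s.
#' @param roi optional logical ROI matrix.
#' @return A one-row data.frame: `epsilon_cps` (boxcar-extrapolated),
#'   `epsilon_cps_uncorrected` (whole-stack ROI mean), `slope_per_s`,
#'   `number`, `bleached_fraction`, `n_pixels`, `n_saturated`.
#' @export
nb_cell_brightness <- function(stack, window = 8L, max_rate = 1e6,
                               roi = NULL) {
  sat <- saturation_mask(stack, max_rate)
  bb <- boxcar_brightness(stack, window = window, roi = roi,
                          sat_mask = sat, pool = "roi")
  rb <- roi_brightness(bb$map, roi = roi, sat_mask = sat)
  bf <- bleached_fraction(stack)
  # whole-stack brightness with the same moment pooling as the windows
  include <- !sat
  if (!is.null(roi)) include <- include & roi
  kbar <- mean(bb$map$mean_counts[include])
  s2 <- mean(bb$map$variance[include])
  eps_unc <- (s2 - kbar) / kbar / stack$pixel_dwell_time
  data.frame(epsilon_cps = bb$extrapolated_epsilon_cps,
             epsilon_cps_uncorrected = eps_unc,
             slope_per_s = bb$slope / stack$pixel_dwell_time,
             number = rb$number,
             bleached_fraction = bf$fraction,
             n_pixels = rb$n_pixels,
             n_saturated = sum(sat))
}
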