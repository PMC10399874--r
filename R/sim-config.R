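#' Simulation configuration
#'
#' Parameters of the synthetic confocal photon-count generators. Defaults
#' describe a typical photon-counting confocal acquisition: 128 x 128 px
#' frames at 50 us dwell (400 nm pixels), 256-px line scans at 472.73 us
#' line time (80 nm pixels), a 0.2 um lateral waist with structure parameter
#' 6, and oligomers whose subunits are independently fluorescent with
#' probability `fluorescence_probability`.
#'
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output for every generator.
#' @param geometry `"raster3d"` (N&B image stacks), `"membrane2d"`
#'   (membrane traces/kymographs) or `"point3d"` (point-FCS traces).
#' @param diffusion_coefficient D in um^2/s.
#' @param n_particles_mean mean occupancy N of the effective detection
#'   volume (point3d), detection area (membrane2d), or observation region of
#'   a raster pixel (raster3d).
#' @param molecular_brightness peak photon count rate per fluorophore at the
#'   centre of the detection volume, counts/s.
#' @param subunits oligomer size (integer >= 1).
#' @param fluorescence_probability per-subunit probability of being
#'   fluorescent, in \[0, 1\].
#' @param bleach_rate irreversible bleaching rate, 1/s, applied per
#'   illuminated fluorophore (trajectory paths) or as an occupancy survival
#'   factor per frame (raster path).
#' @param background_rate uncorrelated background, counts/s per pixel
#'   (raster, kymograph) or per trace (point/membrane traces).
#' @param waist_w0 lateral 1/e^2 beam waist, um.
#' @param structure_parameter S, axial/lateral extent ratio of the detection
#'   volume.
#' @param pixel_dwell_time raster pixel dwell, s.
#' @param pixel_size raster pixel size, um.
#' @param n_frames,height,width raster stack dimensions.
#' @param frame_interval time between frames, s; defaults to
#'   `height * width * pixel_dwell_time`.
#' @param line_time line scan time, s.
#' @param n_pixels pixels per scanned line.
#' @param scan_pixel_size line-scan pixel size, um.
#' @param box_factor periodic simulation box side in units of the detection
#'   extent (w0 laterally, S*w0 axially); must be >= 10.
#' @param blink_on_rate,blink_off_rate telegraph (triplet-like) dark-state
#'   rates, 1/s: `blink_off_rate` is the bright-to-dark rate,
#'   `blink_on_rate` the recovery rate. Both 0 disables blinking.
#' @param laser_power_label free-text metadata.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       geometry = c("raster3d", "membrane2d", "point3d"),
                       diffusion_coefficient = 1.0,
                       n_particles_mean = 5,
                       molecular_brightness = 1e4,
                       subunits = 1L,
                       fluorescence_probability = 1,
                       bleach_rate = 0,
                       background_rate = 0,
                       waist_w0 = 0.2,
                       structure_parameter = 6,
                       pixel_dwell_time = 50e-6,
                       pixel_size = 0.4,
                       n_frames = 100L, height = 128L, width = 128L,
                       frame_interval = NULL,
                       line_time = 472.73e-6, n_pixels = 256L,
                       scan_pixel_size = 0.08,
                       box_factor = 20,
                       blink_on_rate = 0, blink_off_rate = 0,
                       laser_power_label = "") {
  geometry <- match.arg(geometry)
  if (fluorescence_probability < 0 || fluorescence_probability > 1)
    stop("fluorescence_probability must lie in [0, 1]")
  if (subunits < 1) stop("subunits must be >= 1")
  rates <- c(diffusion_coefficient, molecular_brightness, bleach_rate,
             background_rate, blink_on_rate, blink_off_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (pixel_dwell_time <= 0) stop("pixel_dwell_time must be > 0")
  if (line_time <= 0) stop("line_time must be > 0")
  if (waist_w0 <= 0 || structure_parameter <= 0)
    stop("waist_w0 and structure_parameter must be > 0")
  frame_interval <- frame_interval %||%
    (height * width * pixel_dwell_time)
  structure(list(seed = as.integer(seed), geometry = geometry,
                 diffusion_coefficient = diffusion_coefficient,
                 n_particles_mean = n_particles_mean,
                 molecular_brightness = molecular_brightness,
                 subunits = as.integer(subunits),
                 fluorescence_probability = fluorescence_probability,
                 bleach_rate = bleach_rate,
                 background_rate = background_rate,
                 waist_w0 = waist_w0,
                 structure_parameter = structure_parameter,
                 pixel_dwell_time = pixel_dwell_time,
                 pixel_size = pixel_size,
                 n_frames = as.integer(n_frames),
                 height = as.integer(height), width = as.integer(width),
                 frame_interval = frame_interval,
                 line_time = line_time, n_pixels = as.integer(n_pixels),
                 scan_pixel_size = scan_pixel_size,
                 box_factor = box_factor,
                 blink_on_rate = blink_on_rate,
                 blink_off_rate = blink_off_rate,
                 laser_power_label = laser_power_label),
            class = "sim_config")
}

#' Diffusion time of a configuration
#'
#' tau_d = w0^2 / (4 D), the mean dwell time of a molecule in the detection
#' area.
#'
#' @param config a [sim_config()].
#' @return tau_d in seconds.
#' @export
diffusion_time <- function(config) {
  config$waist_w0^2 / (4 * config$diffusion_coefficient)
}

#' Closed-form expectations of a simulation configuration
#'
#' Ground-truth values the analyses should recover. With per-subunit
#' fluorescence probability p and oligomer size s, the fluorophore count per
#' particle is q ~ Binomial(s, p), and brightness-weighted averaging gives
#' the apparent (q^2-weighted) quantities:
#' apparent brightness = gamma * brightness * E\[q^2\]/E\[q\] and apparent
#' particle number N_app = N * E\[q\]^2 / E\[q^2\], with the Gaussian-profile
#' shape factor gamma = 1 (raster fast path, where the per-pixel emission is
#' an idealized compound Poisson process), 1/2 (2D Gaussian detection area),
#' or 1/(2*sqrt(2)) (3D Gaussian volume).
#'
#' @param config a [sim_config()].
#' @return A list: `q_mean`, `q2_mean`, `brightness_ratio`
#'   (E\[q^2\]/E\[q\] = 1 + (s-1)p), `mean_rate` (counts/s), `apparent_N`,
#'   `apparent_brightness` (counts/s), `epsilon_per_dwell` (raster only),
#'   `tau_d` (s).
#' @export
expected_stats <- function(config) {
  s <- config$subunits
  p <- config$fluorescence_probability
  q1 <- s * p
  q2 <- s * p * (1 - p) + (s * p)^2
  ratio <- if (q1 > 0) q2 / q1 else 0   # = 1 + (s - 1) * p
  b <- config$molecular_brightness
  N <- config$n_particles_mean
  gamma <- switch(config$geometry,
                  raster3d = 1,
                  membrane2d = 0.5,
                  point3d = 1 / (2 * sqrt(2)))
  mean_rate <- N * q1 * b * gamma + config$background_rate
  apparent_N <- if (q2 > 0) N * q1^2 / q2 else NA_real_
  list(q_mean = q1, q2_mean = q2, brightness_ratio = ratio,
       mean_rate = mean_rate,
       apparent_N = apparent_N,
       apparent_brightness = gamma * b * ratio,
       epsilon_per_dwell = b * config$pixel_dwell_time * ratio,
       tau_d = diffusion_time(config))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> geometry %s, seed %d\n", x$geometry, x$seed))
  cat(sprintf("  D = %.3g um^2/s, N = %.3g, brightness = %.3g cps, %dmer (p = %.2f)\n",
              x$diffusion_coefficient, x$n_particles_mean,
              x$molecular_brightness, x$subunits,
              x$fluorescence_probability))
  invisible(x)
}
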