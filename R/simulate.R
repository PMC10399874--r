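#' Simulate an N&B photon-count image stack
#'
#' Fast compound-Poisson raster path. Frames are assumed decorrelated (the
#' frame interval, ~0.82 s at default settings, far exceeds cytosolic
#' diffusion times), so each pixel-frame draws an independent occupancy
#' m ~ Poisson(N * survival(t)); the occupants jointly carry
#' Q ~ Binomial(m * subunits, p) fluorophores, emitting
#' Poisson(Q * brightness * dwell) counts; Poisson background adds on top.
#' Irreversible bleaching enters as the occupancy survival factor
#' exp(-bleach_rate * t_frame).
#'
#' @param config a [sim_config()] with `geometry = "raster3d"`.
#' @return An [image_stack()] carrying `config`; attribute `"truth"` holds
#'   the [expected_stats()] closed forms.
#' @export
simulate_nb_stack <- function(config) {
  if (config$geometry != "raster3d")
    stop("simulate_nb_stack requires geometry = 'raster3d'")
  set.seed(config$seed)
  nf <- config$n_frames; h <- config$height; w <- config$width
  npx <- h * w
  n <- nf * npx
  lambda <- config$molecular_brightness * config$pixel_dwell_time
  bg <- config$background_rate * config$pixel_dwell_time
  frame_t <- (seq_len(nf) - 1) * config$frame_interval
  surv <- exp(-config$bleach_rate * frame_t)
  # element i is frame ((i-1) mod nf) + 1 of pixel ((i-1) %/% nf) + 1
  occ <- rpois(n, config$n_particles_mean * rep(surv, times = npx))
  q <- rbinom(n, occ * config$subunits, config$fluorescence_probability)
  counts <- rpois(n, q * lambda + bg)
  stack <- image_stack(array(counts, dim = c(nf, h, w)),
                       pixel_dwell_time = config$pixel_dwell_time,
                       pixel_size = config$pixel_size,
                       frame_interval = config$frame_interval,
                       laser_power_label = config$laser_power_label,
                       config = config)
  attr(stack, "truth") <- expected_stats(config)
  stack
}

#' Simulate a membrane intensity trace (2D Brownian dynamics)
#'
#' Particles diffuse in a periodic 2D box (side `box_factor * w0` laterally
#' and `box_factor * S * w0` along the membrane normal seen by the scan) and
#' emit through an anisotropic Gaussian detection profile
#' exp(-2x^2/w0^2 - 2y^2/(S w0)^2), whose autocorrelation is exactly the
#' two-factor 2D diffusion model with structure parameter S. Counts per bin
#' are Poisson around the summed detection weights; optional bleaching
#' converts fluorophores irreversibly dark with per-step probability
#' proportional to the instantaneous excitation.
#'
#' @param config a [sim_config()] with `geometry = "membrane2d"`.
#' @param duration trace duration in seconds; bins are `config$line_time`.
#' @param positions optional n x 2 matrix of initial particle positions (um,
#'   box-centred); default uniform in the box.
#' @param fluorophores optional integer vector of fluorophore counts per
#'   particle; default Binomial(subunits, p) draws.
#' @return An [intensity_trace()]; attribute `"truth"` holds the
#'   [expected_stats()] closed forms.
#' @export
simulate_membrane_trace <- function(config, duration,
                                    positions = NULL, fluorophores = NULL) {
  if (config$geometry != "membrane2d")
    stop("simulate_membrane_trace requires geometry = 'membrane2d'")
  if (config$box_factor < 10)
    stop("box smaller than 10 * w0: increase box_factor")
  dt <- config$line_time
  n_steps <- round(duration / dt)
  if (n_steps < 2) stop("duration must span at least 2 bins")
  set.seed(config$seed)
  w0 <- config$waist_w0; S <- config$structure_parameter
  bx <- config$box_factor * w0
  by <- config$box_factor * S * w0
  area_eff <- pi * w0^2 * S
  np <- max(1L, round(config$n_particles_mean * bx * by / area_eff))
  if (is.null(positions)) {
    positions <- cbind(runif(np, -bx / 2, bx / 2),
                       runif(np, -by / 2, by / 2))
  } else {
    positions <- as.matrix(positions)
    np <- nrow(positions)
  }
  fluorophores <- fluorophores %||%
    rbinom(np, config$subunits, config$fluorescence_probability)
  counts <- .sim_trace_2d(n_steps, dt,
                          positions[, 1], positions[, 2],
                          as.integer(fluorophores),
                          bx, by,
                          sqrt(2 * config$diffusion_coefficient * dt),
                          w0, S * w0,
                          config$molecular_brightness * dt,
                          config$bleach_rate * dt,
                          config$background_rate * dt)
  tr <- intensity_trace(counts, dt, config = config)
  attr(tr, "truth") <- expected_stats(config)
  tr
}

#' Distribute a membrane trace over a line-scan kymograph
#'
#' Each line's membrane counts are spread multinomially across pixels with a
#' Gaussian spatial profile centred at `membrane_center + drift * line`;
#' per-line totals are conserved exactly. Independent Poisson background
#' (rate `background_rate / n_pixels` per pixel) is added afterwards.
#'
#' @param trace an integer-valued [intensity_trace()] (membrane counts per
#'   line).
#' @param config a [sim_config()] (for `n_pixels`, background, seed).
#' @param membrane_center membrane position in pixels (default
#'   `n_pixels / 2`).
#' @param profile_sigma Gaussian profile width in pixels.
#' @param drift lateral drift in pixels per line.
#' @return A [kymograph()]; attribute `"ground_truth"` records the per-line
#'   centres, profile width, and source trace.
#' @export
simulate_kymograph <- function(trace, config, membrane_center = NULL,
                               profile_sigma = 2, drift = 0) {
  npix <- config$n_pixels
  membrane_center <- membrane_center %||% (npix / 2)
  counts <- trace$counts
  if (any(counts != round(counts)))
    stop("trace counts must be integer photon counts")
  nl <- length(counts)
  centers <- membrane_center + drift * (seq_len(nl) - 1)
  if (any(centers - 3 * profile_sigma < 1) ||
      any(centers + 3 * profile_sigma > npix))
    stop("membrane centre (or drift end point) within 3 sigma of the frame edge")
  set.seed(config$seed + 1L)
  line_id <- rep(seq_len(nl), times = counts)
  px <- pmin(pmax(as.integer(round(rnorm(length(line_id),
                                         mean = centers[line_id],
                                         sd = profile_sigma))), 1L), npix)
  m <- matrix(tabulate(line_id + (px - 1L) * nl, nbins = nl * npix),
              nrow = nl)
  bg_mean <- config$background_rate * trace$dt / npix
  if (bg_mean > 0)
    m <- m + matrix(rpois(nl * npix, bg_mean), nrow = nl)
  ky <- kymograph(m, line_time = trace$dt,
                  pixel_size = config$scan_pixel_size, config = config)
  attr(ky, "ground_truth") <- list(centers = centers,
                                   profile_sigma = profile_sigma,
                                   trace = counts)
  attr(ky, "truth") <- attr(trace, "truth")
  ky
}

#' Simulate a point-detection photon-count trace (3D Brownian dynamics)
#'
#' Particles diffuse in a periodic 3D box and emit through the Gaussian
#' detection volume exp(-2(x^2 + y^2)/w0^2 - 2z^2/(S w0)^2); counts per bin
#' are Poisson. Optional triplet-like blinking is a two-state telegraph
#' process with bright-to-dark rate `blink_off_rate` and recovery rate
#' `blink_on_rate`.
#'
#' @param config a [sim_config()] with `geometry = "point3d"`.
#' @param duration trace duration, seconds.
#' @param dt bin width, seconds (> 0; also the integrator step).
#' @return An [intensity_trace()]; attribute `"truth"` holds the
#'   [expected_stats()] closed forms.
#' @export
simulate_point_trace <- function(config, duration, dt) {
  if (config$geometry != "point3d")
    stop("simulate_point_trace requires geometry = 'point3d'")
  if (dt <= 0) stop("dt must be > 0")
  if (config$box_factor < 10)
    stop("box smaller than 10 * w0: increase box_factor")
  if (config$box_factor < 2 * pi * config$structure_parameter)
    warning("lateral box below 2*pi*S*w0: the slowest lateral diffusion ",
            "mode decays faster than the axial correlation tail, ",
            "distorting G(tau) around S^2*tau_d; increase box_factor or ",
            "lower S")
  n_steps <- round(duration / dt)
  if (n_steps < 2) stop("duration must span at least 2 bins")
  set.seed(config$seed)
  w0 <- config$waist_w0; S <- config$structure_parameter
  bxy <- config$box_factor * w0
  bz <- config$box_factor * S * w0
  vol_eff <- pi^1.5 * w0^3 * S
  np <- max(1L, round(config$n_particles_mean * bxy^2 * bz / vol_eff))
  x0 <- runif(np, -bxy / 2, bxy / 2)
  y0 <- runif(np, -bxy / 2, bxy / 2)
  z0 <- runif(np, -bz / 2, bz / 2)
  q0 <- rbinom(np, config$subunits, config$fluorescence_probability)
  counts <- .sim_trace_3d(n_steps, dt, x0, y0, z0, as.integer(q0),
                          bxy, bz,
                          sqrt(2 * config$diffusion_coefficient * dt),
                          w0, S * w0,
                          config$molecular_brightness * dt,
                          config$bleach_rate * dt,
                          config$background_rate * dt,
                          config$blink_off_rate * dt,
                          config$blink_on_rate * dt)
  tr <- intensity_trace(counts, dt, config = config)
  attr(tr, "truth") <- expected_stats(config)
  tr
}
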