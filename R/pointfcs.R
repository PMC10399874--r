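#' Detection-volume geometry from a calibration fit
#'
#' For a dye of known diffusion coefficient, the lateral waist follows from
#' the fitted diffusion time as w0 = sqrt(4 D tau_d), and the effective
#' detection volume is V_eff = pi^(3/2) w0^3 S.
#'
#' @param tau_d fitted diffusion time, seconds.
#' @param S structure parameter.
#' @param dye_D dye diffusion coefficient, um^2/s.
#' @return A list: `w0` (um), `effective_volume` (um^3).
#' @export
detection_geometry <- function(tau_d, S, dye_D) {
  if (tau_d <= 0 || S <= 0 || dye_D <= 0)
    stop("tau_d, S and dye_D must be > 0")
  w0 <- sqrt(4 * dye_D * tau_d)
  list(w0 = w0, effective_volume = pi^1.5 * w0^3 * S)
}

#' Daily point-FCS calibration of the confocal detection volume
#'
#' Dye traces are grouped into measurements; within each measurement the
#' per-acquisition autocorrelation curves are averaged and the average is
#' fitted with the 3D diffusion + triplet model (S free). Pooled estimates
#' are the mean +/- SD across measurements. If the dye's diffusion
#' coefficient is supplied, the lateral waist w0 = sqrt(4 D tau_d) and the
#' effective volume V_eff = pi^(3/2) w0^3 S are derived.
#'
#' @param traces list of [intensity_trace()] acquisitions (all with the
#'   same bin width and length).
#' @param dye_D optional dye diffusion coefficient, um^2/s.
#' @param measurement_ids optional vector assigning each trace to a
#'   measurement (default: all one measurement).
#' @param m multi-tau lags per octave.
#' @param fit_max_lag drop lags beyond this time from the fit (default one
#'   tenth of the acquisition).
#' @param per_acquisition also fit each acquisition individually.
#' @return An object of class `calibration_result`: pooled `tau_d`, `S`,
#'   `N`, `T`, `tau_T` with `*_sd` spreads, `per_measurement` data.frame,
#'   `w0` and `effective_volume` (only with `dye_D`), `n_measurements`,
#'   `converged`.
#' @export
calibrate <- function(traces, dye_D = NULL, measurement_ids = NULL,
                      m = 16L, fit_max_lag = NULL,
                      per_acquisition = FALSE) {
  if (!length(traces)) stop("at least one acquisition is required")
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  measurement_ids <- measurement_ids %||% rep(1L, length(traces))
  if (length(measurement_ids) != length(traces))
    stop("measurement_ids must match the number of traces")
  dt <- traces[[1]]$dt
  curves <- lapply(traces, compute_acf, m = m, n_segments = 1L)
  lags <- curves[[1]]$lags
  fit_max_lag <- fit_max_lag %||%
    (length(traces[[1]]$counts) * dt / 10)
  tau_T_max <- .default_bounds()$upper[["tau_T"]]
  triplet_resolved <- lags[1] <= tau_T_max
  if (!triplet_resolved)
    message("first lag (", format(lags[1]), " s) cannot resolve triplet ",
            "kinetics up to ", format(tau_T_max),
            " s; fitting with T fixed at 0")

  groups <- split(seq_along(traces), measurement_ids)
  fits <- lapply(groups, function(idx) {
    Gm <- vapply(curves[idx], function(cu) cu$G, numeric(length(lags)))
    Gm <- matrix(Gm, nrow = length(lags))
    G_avg <- rowMeans(Gm)
    # per-lag SE from the spread across acquisitions (needs >= 3)
    sd_G <- if (ncol(Gm) >= 3)
      apply(Gm, 1, sd) / sqrt(ncol(Gm)) else NULL
    keep <- lags <= fit_max_lag
    curve <- correlation_curve(lags[keep], G_avg[keep],
                               sd_G = sd_G[keep], dt = dt)
    # a triplet decaying within the first lag is unresolvable: fix T = 0
    fixed <- if (!triplet_resolved) list(T = 0, tau_T = tau_T_max) else
      list()
    try(fit_acf(curve, model = "3d_triplet", fixed = fixed,
                weights = if (is.null(sd_G)) "none" else "sd"),
        silent = TRUE)
  })
  ok <- vapply(fits, function(f)
    !inherits(f, "try-error") && f$converged, logical(1))
  if (!any(ok)) stop("all calibration fits failed to converge")

  pn <- c("N", "tau_d", "S", "T", "tau_T")
  per <- do.call(rbind, lapply(which(ok), function(i)
    data.frame(measurement = names(groups)[i],
               t(fits[[i]]$estimates[pn]))))
  pooled <- colMeans(per[pn])
  spread <- vapply(per[pn], function(v)
    if (length(v) > 1) sd(v) else NA_real_, numeric(1))

  res <- list(tau_d = pooled[["tau_d"]], tau_d_sd = spread[["tau_d"]],
              S = pooled[["S"]], S_sd = spread[["S"]],
              N = pooled[["N"]], N_sd = spread[["N"]],
              T = pooled[["T"]], tau_T = pooled[["tau_T"]],
              per_measurement = per,
              n_measurements = sum(ok),
              n_failed = sum(!ok),
              converged = TRUE,
              triplet_resolved = triplet_resolved,
              dye_D = dye_D)
  if (!is.null(dye_D)) {
    geom <- detection_geometry(res$tau_d, res$S, dye_D)
    res$w0 <- geom$w0
    res$effective_volume <- geom$effective_volume
  }
  if (per_acquisition)
    res$acquisition_fits <- lapply(curves, function(cu) {
      keep <- cu$lags <= fit_max_lag
      try(fit_acf(correlation_curve(cu$lags[keep], cu$G[keep], dt = dt),
                  model = "3d_triplet"), silent = TRUE)
    })
  structure(res, class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d measurement(s): tau_d = %.4g us, S = %.3g, N = %.3g, T = %.3g\n",
              x$n_measurements, x$tau_d * 1e6, x$S, x$N, x$T))
  if (!is.null(x$w0))
    cat(sprintf("  w0 = %.4g um, V_eff = %.4g um^3 (dye D = %.3g um^2/s)\n",
                x$w0, x$effective_volume, x$dye_D))
  invisible(x)
}

#' Structure parameter to fix for the day's cell measurements
#'
#' Returns the pooled calibration S, flagging values outside a
#' plausibility band (default 3 to 15; typical well-aligned confocal
#' calibrations fall around 5 to 9).
#'
#' @param result a converged [calibrate()] result.
#' @param band length-2 numeric plausibility band.
#' @return A list: `S`, `in_band`.
#' @export
fixed_s_for_day <- function(result, band = c(3, 15)) {
  if (!isTRUE(result$converged)) stop("calibration did not converge")
  S <- result$S
  list(S = S, in_band = S >= band[1] && S <= band[2])
}
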