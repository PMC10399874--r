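#' Two-dimensional Brownian diffusion ACF model
#'
#' G(tau) = offset + (1/N) (1 + tau/tau_d)^(-1/2)
#' (1 + tau/(tau_d S^2))^(-1/2), the autocorrelation of free 2D Brownian
#' diffusion through an elliptical Gaussian detection area with axis ratio
#' S (the sFCS geometry: beam waist w0 laterally, S w0 along the membrane
#' normal). `S = Inf` drops the second factor.
#'
#' @param tau lag times, seconds (>= 0).
#' @param N mean particle number in the detection area (> 0).
#' @param tau_d diffusion time, seconds (> 0).
#' @param S structure parameter (> 0; may be `Inf`).
#' @param offset baseline.
#' @return G values, same length as `tau`.
#' @export
acf_2d <- function(tau, N, tau_d, S, offset = 0) {
  if (N <= 0 || tau_d <= 0 || S <= 0)
    stop("N, tau_d and S must be > 0")
  if (any(tau < 0)) stop("tau must be >= 0")
  ax <- (1 + tau / tau_d)^(-0.5)
  sec <- if (is.finite(S)) (1 + tau / (tau_d * S^2))^(-0.5) else 1
  offset + ax * sec / N
}

#' 3D diffusion plus triplet ACF model
#'
#' G(tau) = offset + (1 + T/(1-T) exp(-tau/tau_T)) (1/N)
#' (1 + tau/tau_d)^(-1) (1 + tau/(tau_d S^2))^(-1/2): free 3D diffusion
#' through a Gaussian detection volume of axial/lateral ratio S, with the
#' standard multiplicative triplet (dark-state) term of fraction T and
#' relaxation time tau_T. `T = 0` reduces exactly to the pure 3D model.
#'
#' @param tau lag times, seconds (>= 0).
#' @inheritParams acf_2d
#' @param T triplet fraction in \[0, 1).
#' @param tau_T triplet relaxation time, seconds.
#' @return G values.
#' @export
acf_3d_triplet <- function(tau, N, tau_d, S, T = 0, tau_T = 1e-5,
                           offset = 0) {
  if (N <= 0 || tau_d <= 0 || S <= 0)
    stop("N, tau_d and S must be > 0")
  if (T < 0 || T >= 1) stop("T must lie in [0, 1)")
  if (any(tau < 0)) stop("tau must be >= 0")
  trip <- if (T > 0) 1 + T / (1 - T) * exp(-tau / tau_T) else 1
  sec <- if (is.finite(S)) (1 + tau / (tau_d * S^2))^(-0.5) else 1
  offset + trip * sec / (N * (1 + tau / tau_d))
}

.model_fun <- function(model) {
  switch(model,
         "2d" = function(tau, p)
           acf_2d(tau, p[["N"]], p[["tau_d"]], p[["S"]], p[["offset"]]),
         "3d_triplet" = function(tau, p)
           acf_3d_triplet(tau, p[["N"]], p[["tau_d"]], p[["S"]],
                          p[["T"]], p[["tau_T"]], p[["offset"]]),
         stop("unknown model: ", model))
}

.model_params <- function(model) {
  switch(model,
         "2d" = c("N", "tau_d", "S", "offset"),
         "3d_triplet" = c("N", "tau_d", "S", "T", "tau_T", "offset"))
}

.default_bounds <- function() {
  list(lower = c(N = 1e-3, tau_d = 1e-6, S = 0.5, T = 0,
                 tau_T = 1e-7, offset = -1),
       upper = c(N = 1e6, tau_d = 10, S = 100, T = 0.5,
                 tau_T = 2e-5, offset = 1))
}

#' Initial parameter guess from a correlation curve
#'
#' N0 is the reciprocal of the early-lag plateau (mean G over the first 3
#' lags); tau_d0 is the first lag at which G falls below half that plateau.
#' The triplet fraction starts at 0.
#'
#' @param curve a [correlation_curve()].
#' @param model `"2d"` or `"3d_triplet"`.
#' @return Named numeric vector of starting values.
#' @export
initial_guess <- function(curve, model = c("2d", "3d_triplet")) {
  model <- match.arg(model)
  G <- curve$G; lags <- curve$lags
  k <- min(3L, length(G))
  plateau <- mean(G[seq_len(k)])
  if (!is.finite(plateau) || plateau <= 0)
    stop("non-positive early-lag plateau; not a decaying correlation curve")
  if (mean(tail(G, k)) > plateau)
    stop("G increases with lag; not a decaying correlation curve")
  below <- which(G < plateau / 2)
  half_lag <- if (length(below)) lags[below[1]] else lags[length(lags)] / 2
  # G reaches half amplitude near 3 tau_d (2D, large S) or tau_d (3D)
  tau_d0 <- if (model == "2d") half_lag / 3 else half_lag
  init <- c(N = 1 / plateau, tau_d = tau_d0, S = 5, offset = 0)
  if (model == "3d_triplet")
    init <- c(init, T = 0, tau_T = max(lags[1], 1e-6))
  init[.model_params(model)]
}

#' Fit an FCS model to a correlation curve
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) with box
#' bounds, optional per-lag SD weighting, and fixed parameters (e.g. the
#' structure parameter S fixed to the daily calibration value).
#'
#' @param curve a [correlation_curve()] with >= 8 lags.
#' @param model `"2d"` or `"3d_triplet"`.
#' @param init optional named starting values; defaults to
#'   [initial_guess()] plus midpoints for unset parameters.
#' @param fixed named list/vector of parameters held fixed.
#'
#' @details Default bounds are N in (1e-3, 1e6), tau_d in (1 us, 10 s),
#'   T in \[0, 0.5\] and tau_T in (0.1 us, 20 us). The tau_T ceiling keeps
#'   the triplet term in the photophysically plausible microsecond range of
#'   organic dyes and fluorescent proteins; without it the triplet factor
#'   can exchange with the diffusion terms and act as a spurious second
#'   diffusing component. Pass `upper = c(tau_T = ...)` for slower
#'   dark-state kinetics.
#' @param weights `"none"` (default) or `"sd"` (use `curve$sd_G`).
#' @param lower,upper optional named bound overrides.
#' @return An object of class `fit_result`: `estimates` (all parameters,
#'   fixed included), `se` (NA for fixed parameters), `reduced_chisq`,
#'   `converged`, `fixed`, `model`, `message`, `df`.
#' @export
fit_acf <- function(curve, model = c("2d", "3d_triplet"), init = NULL,
                    fixed = list(), weights = c("none", "sd"),
                    lower = NULL, upper = NULL) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  tau <- curve$lags; G <- curve$G
  if (length(tau) < 8) stop("need at least 8 lag points")
  if (all(abs(G - G[1]) < .Machine$double.eps * 10))
    stop("degenerate curve: all G values equal")
  pnames <- .model_params(model)
  fixed <- unlist(fixed)
  if (length(fixed) && !all(names(fixed) %in% pnames))
    stop("unknown fixed parameter(s): ",
         paste(setdiff(names(fixed), pnames), collapse = ", "))
  free <- setdiff(pnames, names(fixed))
  if (!length(free)) stop("no free parameters")

  start <- initial_guess(curve, model)
  if (!is.null(init)) start[names(init)] <- unlist(init)
  start[names(fixed)] <- fixed
  bounds <- .default_bounds()
  lo <- bounds$lower[pnames]; up <- bounds$upper[pnames]
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) up[names(upper)] <- unlist(upper)
  start[free] <- pmin(pmax(start[free], lo[free]), up[free])

  sig <- if (weights == "sd" && !is.null(curve$sd_G)) {
    s <- curve$sd_G
    s[!is.finite(s) | s <= 0] <- median(s[is.finite(s) & s > 0])
    s
  } else rep(1, length(G))
  f <- .model_fun(model)
  full <- start
  resid_fn <- function(par) {
    full[free] <- par
    (G - f(tau, full)) / sig
  }
  fit <- minpack.lm::nls.lm(par = start[free], fn = resid_fn,
                            lower = lo[free], upper = up[free],
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- start
  est[free] <- fit$par
  df <- length(G) - length(free)
  rss <- sum(fit$fvec^2)
  red_chi <- if (df > 0) rss / df else NA_real_
  se <- rep(NA_real_, length(pnames))
  names(se) <- pnames
  cov <- try(solve(fit$hessian) * red_chi, silent = TRUE)
  if (!inherits(cov, "try-error")) {
    dg <- diag(cov)
    dg[dg < 0] <- NA_real_
    se[free] <- sqrt(dg)
  }
  structure(list(estimates = est, se = se,
                 reduced_chisq = red_chi,
                 converged = fit$info %in% 1:4,
                 fixed = names(fixed), free = free,
                 model = model, message = fit$message, df = df,
                 lower = lo, upper = up, init = start),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model %s, %s (red. chi^2 = %.4g)\n", x$model,
              if (x$converged) "converged" else "NOT converged",
              x$reduced_chisq))
  for (p in names(x$estimates)) {
    tag <- if (p %in% x$fixed) " (fixed)" else
      sprintf(" +/- %.3g", x$se[p])
    cat(sprintf("  %-7s %.6g%s\n", p, x$estimates[p], tag))
  }
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$estimates
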