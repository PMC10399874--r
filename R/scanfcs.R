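# Gaussian + constant fit of one averaged line profile; returns NULL on
# failure. Used block-wise by detect_membrane().
.fit_profile <- function(profile) {
  npix <- length(profile)
  px <- seq_len(npix)
  bg0 <- median(profile)
  sm <- stats::filter(profile, rep(1 / 5, 5), sides = 2)
  c0 <- which.max(ifelse(is.na(sm), -Inf, sm))
  a0 <- max(profile[c0] - bg0, 1e-8)
  resid_fn <- function(p)
    profile - (p[4] + p[1] * exp(-(px - p[2])^2 / (2 * p[3]^2)))
  fit <- try(minpack.lm::nls.lm(
    par = c(a0, c0, 2, bg0), fn = resid_fn,
    lower = c(0, 1, 0.3, 0), upper = c(Inf, npix, npix / 4, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 100)),
    silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4)) return(NULL)
  p <- fit$par
  # a real membrane peak stands clear of the noise and explains most of
  # the profile variance; a Gaussian latched onto a noise spike does not
  r2 <- 1 - sum(fit$fvec^2) / sum((profile - mean(profile))^2)
  if (p[1] <= 5 * sd(fit$fvec) || r2 < 0.2) return(NULL)
  list(amplitude = p[1], center = p[2], sigma = p[3], background = p[4])
}

#' Locate the membrane in a line-scan kymograph
#'
#' Lines are averaged in consecutive blocks of `block_size`; each block's
#' mean profile is fitted with a Gaussian peak plus a constant background,
#' giving a sub-pixel membrane centre trajectory. Blocks whose peak fit
#' fails (no convergence, or amplitude not above noise) are flagged.
#'
#' @param kymo a [kymograph()].
#' @param block_size lines per block (default 1000); at least 2 complete
#'   blocks are required.
#' @return An object of class `membrane_localization`: a data.frame
#'   `blocks` (block, line_mid, center, sigma, amplitude, background,
#'   converged) plus `block_size` and `n_lines`.
#' @export
detect_membrane <- function(kymo, block_size = 1000L) {
  counts <- kymo$counts
  nl <- nrow(counts)
  nb <- nl %/% block_size
  if (nb < 2) stop("need at least 2 complete blocks of ", block_size,
                   " lines")
  rows <- lapply(seq_len(nb), function(b) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    f <- .fit_profile(colMeans(counts[idx, , drop = FALSE]))
    data.frame(block = b, line_mid = mean(idx),
               center = if (is.null(f)) NA_real_ else f$center,
               sigma = if (is.null(f)) NA_real_ else f$sigma,
               amplitude = if (is.null(f)) NA_real_ else f$amplitude,
               background = if (is.null(f)) NA_real_ else f$background,
               converged = !is.null(f))
  })
  blocks <- do.call(rbind, rows)
  if (!any(blocks$converged))
    stop("no block yields a convergent membrane peak fit")
  structure(list(blocks = blocks, block_size = block_size, n_lines = nl),
            class = "membrane_localization")
}

#' @export
print.membrane_localization <- function(x, ...) {
  ok <- x$blocks$converged
  cat(sprintf("<membrane_localization> %d blocks (%d converged), centre %.2f +/- %.2f px, sigma %.2f px\n",
              nrow(x$blocks), sum(ok), mean(x$blocks$center[ok]),
              sd(x$blocks$center[ok]), mean(x$blocks$sigma[ok])))
  invisible(x)
}

#' Correct lateral membrane movement line-by-line
#'
#' Per-line membrane centres are interpolated linearly between block
#' centres, and each line is shifted by the negated integer-pixel offset
#' from the mean centre (circular shift, so per-line count totals are
#' conserved exactly); the fractional remainder is recorded, not resampled,
#' preserving the photon-count statistics.
#'
#' @param kymo a [kymograph()].
#' @param loc a [detect_membrane()] result.
#' @return The aligned [kymograph()] with attribute `"alignment"` (list:
#'   `center_ref`, `shifts`, `residual`).
#' @export
align_lines <- function(kymo, loc) {
  blocks <- loc$blocks[loc$blocks$converged, ]
  nl <- nrow(kymo$counts)
  npix <- ncol(kymo$counts)
  centers <- if (nrow(blocks) == 1) rep(blocks$center, nl) else
    approx(blocks$line_mid, blocks$center, xout = seq_len(nl),
           rule = 2)$y
  center_ref <- mean(centers)
  shifts <- round(center_ref - centers)
  if (max(abs(shifts)) > 0.1 * npix)
    stop("alignment shift exceeds 10% of the scanned line")
  m <- kymo$counts
  for (s in unique(shifts[shifts != 0])) {
    sel <- shifts == s
    k <- ((s %% npix) + npix) %% npix
    if (k > 0)
      m[sel, ] <- m[sel, c((npix - k + 1):npix, 1:(npix - k)), drop = FALSE]
  }
  out <- kymograph(m, kymo$line_time, kymo$pixel_size, kymo$config)
  attr(out, "alignment") <- list(center_ref = center_ref, shifts = shifts,
                                 residual = (center_ref - centers) - shifts)
  attr(out, "ground_truth") <- attr(kymo, "ground_truth")
  attr(out, "truth") <- attr(kymo, "truth")
  out
}

#' Extract the membrane intensity trace
#'
#' Per line, counts are summed inside a window of +/-
#' `halfwidth_sigmas * sigma` pixels around the aligned membrane centre;
#' the constant background level, estimated from pixels farther than twice
#' the window half-width from the centre, is subtracted (times the window
#' width). Bins negative after subtraction are clamped to zero and counted.
#'
#' @param aligned an [align_lines()] output (an unaligned kymograph also
#'   works; the mean localized centre is used).
#' @param loc the [detect_membrane()] result.
#' @param halfwidth_sigmas window half-width in units of the fitted profile
#'   sigma (default 2.5).
#' @return An [intensity_trace()] with `dt = line_time` and attribute
#'   `"extraction"` (window pixels, background level per pixel per line,
#'   number of clamped bins).
#' @export
membrane_trace <- function(aligned, loc, halfwidth_sigmas = 2.5) {
  counts <- aligned$counts
  npix <- ncol(counts)
  al <- attr(aligned, "alignment")
  blocks <- loc$blocks[loc$blocks$converged, ]
  center <- if (!is.null(al)) al$center_ref else mean(blocks$center)
  sigma <- mean(blocks$sigma)
  halfw <- halfwidth_sigmas * sigma
  px <- seq_len(npix)
  win <- which(abs(px - center) <= halfw)
  if (!length(win) || min(win) <= 1 || max(win) >= npix)
    stop("summation window collides with the image edge")
  bgpix <- which(abs(px - center) > 2 * halfw)
  bg_level <- if (length(bgpix)) mean(counts[, bgpix]) else 0
  raw <- rowSums(counts[, win, drop = FALSE]) - bg_level * length(win)
  clamped <- sum(raw < 0)
  tr <- intensity_trace(pmax(raw, 0), dt = aligned$line_time,
                        config = aligned$config)
  attr(tr, "extraction") <- list(window = win, background = bg_level,
                                 n_clamped = clamped, center = center,
                                 sigma = sigma)
  attr(tr, "truth") <- attr(aligned, "truth")
  tr
}

# Plain products-based ACF values of x at integer lags (in bins):
# G(k) = mean(x_i x_{i+k}) / mean(x)^2 - 1.
.acf_at_lags <- function(x, lags_bins, mu = mean(x)) {
  n <- length(x)
  vapply(lags_bins, function(k) {
    if (k >= n) return(NA_real_)
    mean(x[1:(n - k)] * x[(k + 1):n]) / mu^2 - 1
  }, numeric(1))
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' G(tau) = <F(t) F(t+tau)> / <F>^2 - 1 on a quasi-logarithmic multi-tau
#' grid: the first 2m lags at the native bin width, then m lags per octave
#' on a trace pairwise-binned by 2 at each octave. The reported G is always
#' the plain full-trace estimator; segmenting the trace (default 8
#' segments) supplies a per-lag standard error and flags segments whose
#' mean intensity deviates by more than 3 SD from the segment-mean average.
#'
#' @param trace an [intensity_trace()] with >= 2^10 bins.
#' @param m lags per octave (default 16).
#' @param n_segments segments for the per-lag SD (default 8; 1 disables).
#' @return A [correlation_curve()].
#' @export
compute_acf <- function(trace, m = 16L, n_segments = 8L) {
  x <- as.numeric(trace$counts)
  n <- length(x)
  if (n < 1024) stop("trace must have at least 2^10 bins")
  mu <- mean(x)
  if (mu == 0) stop("zero-mean trace")
  dt <- trace$dt

  lag_list <- list(seq_len(2L * m))
  level_of <- list(rep(0L, 2L * m))
  xs <- list(x)
  lev <- 0L
  xl <- x
  while (TRUE) {
    nl <- length(xl)
    nl2 <- nl %/% 2L
    if (nl2 < 4L * m) break
    xl <- (xl[seq(1, 2 * nl2, by = 2)] + xl[seq(2, 2 * nl2, by = 2)]) / 2
    lev <- lev + 1L
    lag_list[[lev + 1L]] <- (m + 1L):(2L * m)
    level_of[[lev + 1L]] <- rep(lev, m)
    xs[[lev + 1L]] <- xl
  }
  levels <- unlist(level_of)
  klags <- unlist(lag_list)
  G <- numeric(length(klags))
  for (l in unique(levels)) {
    sel <- levels == l
    G[sel] <- .acf_at_lags(xs[[l + 1L]], klags[sel])
  }
  lags_s <- klags * 2^levels * dt
  keep <- !is.na(G)
  lags_s <- lags_s[keep]; G <- G[keep]
  levels <- levels[keep]; klags <- klags[keep]

  sd_G <- NULL; n_rejected <- 0L
  if (n_segments > 1L) {
    seg_len <- n %/% n_segments
    seg_G <- matrix(NA_real_, n_segments, length(G))
    seg_mu <- numeric(n_segments)
    for (s in seq_len(n_segments)) {
      xseg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
      seg_mu[s] <- mean(xseg)
      if (seg_mu[s] == 0) next
      xl <- xseg
      for (l in unique(levels)) {
        if (l > 0) {
          nl2 <- length(xl) %/% 2L
          xl <- (xl[seq(1, 2 * nl2, by = 2)] +
                 xl[seq(2, 2 * nl2, by = 2)]) / 2
        }
        idx <- which(levels == l)
        ks <- klags[idx]
        ok <- ks < length(xl) / 2
        seg_G[s, idx[ok]] <- .acf_at_lags(xl, ks[ok])
      }
    }
    nseg_ok <- colSums(!is.na(seg_G))
    sd_G <- apply(seg_G, 2, sd, na.rm = TRUE) / sqrt(pmax(nseg_ok, 1))
    dev <- abs(seg_mu - mean(seg_mu))
    n_rejected <- sum(dev > 3 * sd(seg_mu))
  }
  correlation_curve(lags_s, G, sd_G = sd_G, n_segments = n_segments,
                    n_rejected = n_rejected, dt = dt)
}

#' Molecular brightness from an sFCS measurement
#'
#' B = (<I>) / N: the mean fluorescence intensity of the membrane trace
#' divided by the fitted particle number, in counts/s/molecule.
#'
#' @param trace the membrane [intensity_trace()].
#' @param fit a converged [fit_acf()] result with parameter `N`.
#' @return Brightness in counts/s/molecule.
#' @export
sfcs_brightness <- function(trace, fit) {
  if (!fit$converged) stop("fit did not converge; no brightness reported")
  N <- unname(fit$estimates["N"])
  if (!is.finite(N) || N <= 0) stop("fitted N must be > 0")
  (mean(trace$counts) / trace$dt) / N
}

#' Full sFCS analysis of one kymograph
#'
#' Composition of [detect_membrane()], [align_lines()],
#' [membrane_trace()], [compute_acf()], [fit_acf()] (2D model, S fixed by
#' default), [sfcs_brightness()] and [bleached_fraction()]; every stage's
#' diagnostics are retained, and errors are re-thrown with the failing
#' stage named.
#'
#' @param kymo a [kymograph()].
#' @param S structure parameter to fix during the fit (e.g. from daily
#'   calibration).
#' @param block_size lines per localization block.
#' @param halfwidth_sigmas trace window half-width in profile sigmas.
#' @param m multi-tau lags per octave.
#' @param n_segments ACF segments.
#' @param fix_S fix S to the supplied value (default) or float it.
#' @param fit_max_lag drop lags beyond this time from the fit. The default
#'   reaches to ~5 S^2 tau_d (from the initial guess), past the axial tail
#'   of the model but short of the noise-only region that otherwise
#'   destabilizes tau_d.
#' @return A list of class `sfcs_record`: `localization`, `alignment`,
#'   `trace`, `curve`, `fit`, `N`, `tau_d`, `S_used`, `brightness_cps`,
#'   `mean_rate_cps`, `bleached_fraction`.
#' @export
run_sfcs <- function(kymo, S, block_size = 1000L, halfwidth_sigmas = 2.5,
                     m = 16L, n_segments = 8L, fix_S = TRUE,
                     fit_max_lag = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  loc <- stage("detect_membrane", detect_membrane(kymo, block_size))
  aligned <- stage("align_lines", align_lines(kymo, loc))
  trace <- stage("membrane_trace",
                 membrane_trace(aligned, loc, halfwidth_sigmas))
  curve <- stage("compute_acf", compute_acf(trace, m = m,
                                            n_segments = n_segments))
  # fit out to where the model has fully decayed (~5 S^2 tau_d covers the
  # axial tail); lags beyond that are correlated noise that destabilizes
  # tau_d against the offset
  fit_max_lag <- fit_max_lag %||% {
    tau_d0 <- initial_guess(curve, "2d")[["tau_d"]]
    min(max(5 * S^2 * tau_d0, 50 * tau_d0),
        length(trace$counts) * trace$dt / 10)
  }
  keep <- curve$lags <= fit_max_lag
  fcurve <- correlation_curve(curve$lags[keep], curve$G[keep],
                              sd_G = curve$sd_G[keep],
                              n_segments = curve$n_segments,
                              n_rejected = curve$n_rejected,
                              dt = curve$dt)
  fixed <- if (fix_S) list(S = S) else list()
  fit <- stage("fit_acf", fit_acf(fcurve, model = "2d", fixed = fixed,
                                  init = if (!fix_S) c(S = S) else NULL,
                                  weights = if (is.null(fcurve$sd_G))
                                    "none" else "sd"))
  B <- stage("sfcs_brightness", sfcs_brightness(trace, fit))
  bf <- stage("bleached_fraction", bleached_fraction(trace))
  structure(list(localization = loc,
                 alignment = attr(aligned, "alignment"),
                 trace = trace, curve = curve, fit = fit,
                 N = unname(fit$estimates["N"]),
                 tau_d = unname(fit$estimates["tau_d"]),
                 S_used = unname(fit$estimates["S"]),
                 brightness_cps = B,
                 mean_rate_cps = mean(trace$counts) / trace$dt,
                 bleached_fraction = bf$fraction),
            class = "sfcs_record")
}

#' @export
print.sfcs_record <- function(x, ...) {
  cat(sprintf("<sfcs_record> N = %.3g, tau_d = %.4g ms, B = %.4g counts/s/molecule, bleached %.1f%%\n",
              x$N, x$tau_d * 1e3, x$brightness_cps,
              100 * x$bleached_fraction))
  invisible(x)
}
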