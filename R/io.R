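.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

.require_meta <- function(meta, field, override) {
  if (!is.null(override)) return(override)
  v <- meta[[field]]
  if (is.null(v) || !is.finite(as.numeric(v)))
    stop("missing acquisition metadata: '", field,
         "' (no sidecar value and no explicit argument)")
  as.numeric(v)
}

.pages_to_uint16 <- function(pages) {
  lapply(pages, function(p) {
    if (max(p) > 65535) stop("counts exceed the 16-bit range")
    p / 65535
  })
}

.read_tiff_pages <- function(path, convert = FALSE) {
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  float_typed <- any(info$bits.per.sample > 16)
  if (float_typed && !convert)
    stop("float-typed TIFF; pass convert = TRUE to round to integer counts")
  # as.is returns raw integer counts; float pages come back as stored
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !float_typed)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, round)
}

#' Write / read an image stack as multi-page TIFF + JSON sidecar
#'
#' Counts are stored losslessly as 16-bit unsigned TIFF pages (one page per
#' frame); dwell time, pixel size, frame interval and any generating
#' configuration go into a `<path>.json` sidecar. Reading restores counts
#' bit-exactly; metadata comes from the sidecar, overridable by arguments,
#' and a missing required field is an error, never a silent default.
#'
#' @param stack an [image_stack()].
#' @param path TIFF output path.
#' @return `write_stack`: the path, invisibly. `read_stack`: an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$counts)
  pages <- lapply(seq_len(d[1]), function(f)
    matrix(stack$counts[f, , ], d[2], d[3]))
  tiff::writeTIFF(.pages_to_uint16(pages), path, bits.per.sample = 16,
                  compression = "none")
  .write_sidecar(path, list(modality = "nb_stack",
                            pixel_dwell_time = stack$pixel_dwell_time,
                            pixel_size = stack$pixel_size,
                            frame_interval = stack$frame_interval,
                            laser_power_label = stack$laser_power_label,
                            seed = stack$config$seed,
                            config = unclass(stack$config)))
  invisible(path)
}

#' @rdname write_stack
#' @param pixel_dwell_time,pixel_size,frame_interval metadata overrides
#'   (seconds / micrometres / seconds); required if the sidecar is absent.
#' @param convert allow reading float-typed TIFF by rounding.
#' @export
read_stack <- function(path, pixel_dwell_time = NULL, pixel_size = NULL,
                       frame_interval = NULL, convert = FALSE) {
  pages <- .read_tiff_pages(path, convert)
  meta <- .read_sidecar(path)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  counts <- array(0L, dim = c(length(pages), h, w))
  for (f in seq_along(pages)) counts[f, , ] <- as.integer(pages[[f]])
  image_stack(counts,
              pixel_dwell_time = .require_meta(meta, "pixel_dwell_time",
                                               pixel_dwell_time),
              pixel_size = .require_meta(meta, "pixel_size", pixel_size),
              frame_interval = .require_meta(meta, "frame_interval",
                                             frame_interval),
              laser_power_label = meta$laser_power_label %||% "")
}

#' Write / read a kymograph as multi-page TIFF + JSON sidecar
#'
#' Lines are stored in blocks of `block_lines` rows per 16-bit page; the
#' line time and pixel size go into the sidecar.
#'
#' @param kymo a [kymograph()].
#' @param path TIFF output path.
#' @param block_lines kymograph lines per TIFF page.
#' @return `write_kymograph`: the path, invisibly. `read_kymograph`: a
#'   [kymograph()].
#' @export
write_kymograph <- function(kymo, path, block_lines = 1024L) {
  nl <- nrow(kymo$counts)
  starts <- seq(1L, nl, by = block_lines)
  pages <- lapply(starts, function(s)
    kymo$counts[s:min(s + block_lines - 1L, nl), , drop = FALSE])
  tiff::writeTIFF(.pages_to_uint16(pages), path, bits.per.sample = 16,
                  compression = "none")
  .write_sidecar(path, list(modality = "kymograph",
                            line_time = kymo$line_time,
                            pixel_size = kymo$pixel_size,
                            seed = kymo$config$seed,
                            config = unclass(kymo$config)))
  invisible(path)
}

#' @rdname write_kymograph
#' @param line_time,pixel_size metadata overrides; required if the sidecar
#'   is absent.
#' @param convert allow reading float-typed TIFF by rounding.
#' @export
read_kymograph <- function(path, line_time = NULL, pixel_size = NULL,
                           convert = FALSE) {
  pages <- .read_tiff_pages(path, convert)
  meta <- .read_sidecar(path)
  counts <- do.call(rbind, pages)
  storage.mode(counts) <- "integer"
  kymograph(counts,
            line_time = .require_meta(meta, "line_time", line_time),
            pixel_size = .require_meta(meta, "pixel_size", pixel_size))
}

#' Write / read an intensity trace as CSV
#'
#' Two columns, `time_s` and `counts`; the bin width is recovered from the
#' time column on reading.
#'
#' @param trace an [intensity_trace()].
#' @param path CSV path.
#' @return `write_trace`: the path, invisibly. `read_trace`: an
#'   [intensity_trace()].
#' @export
write_trace <- function(trace, path) {
  n <- length(trace$counts)
  write.csv(data.frame(time_s = (seq_len(n) - 1) * trace$dt,
                       counts = trace$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "counts") %in% names(df)))
    stop("trace CSV must have columns time_s and counts")
  intensity_trace(df$counts, dt = median(diff(df$time_s)))
}

#' Write / read a correlation curve as CSV
#'
#' Columns `lag_s`, `G` and (when available) `sd_G`.
#'
#' @param curve a [correlation_curve()].
#' @param path CSV path.
#' @return `write_curve`: the path, invisibly. `read_curve`: a
#'   [correlation_curve()].
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(lag_s = curve$lags, G = curve$G)
  if (!is.null(curve$sd_G)) df$sd_G <- curve$sd_G
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  correlation_curve(df$lag_s, df$G, sd_G = df$sd_G)
}

#' Write a fit result as JSON
#'
#' Serializes estimates, standard errors, the reduced chi-square, the
#' fixed-parameter set, bounds and starting values.
#'
#' @param fit a [fit_acf()] result.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(model = fit$model,
                            estimates = as.list(fit$estimates),
                            se = as.list(fit$se),
                            reduced_chisq = fit$reduced_chisq,
                            converged = fit$converged,
                            fixed = fit$fixed,
                            lower = as.list(fit$lower),
                            upper = as.list(fit$upper),
                            init = as.list(fit$init)),
                       path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
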