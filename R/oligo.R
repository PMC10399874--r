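#' One per-cell brightness record
#'
#' Row constructor for the tidy table consumed by the pf workflow. Each row
#' is one cell's molecular brightness with its provenance: construct
#' species (monomer or tandem dimer), fluorophore, measurement day, method
#' and condition.
#'
#' @param cell_id cell identifier.
#' @param species `"monomer"` or `"dimer"`.
#' @param fluorophore fluorophore name.
#' @param day experiment day / session id.
#' @param brightness molecular brightness, counts/s/molecule (> 0).
#' @param method `"nandb"` or `"sfcs"`.
#' @param condition condition label (e.g. pH), default "".
#' @return One-row data.frame.
#' @export
brightness_record <- function(cell_id, species, fluorophore, day,
                              brightness, method = c("nandb", "sfcs"),
                              condition = "") {
  method <- match.arg(method)
  species <- match.arg(species, c("monomer", "dimer"))
  if (!is.finite(brightness) || brightness <= 0)
    stop("brightness must be > 0")
  if (missing(day) || is.na(day)) stop("a day/session id is required")
  data.frame(cell_id = as.character(cell_id), species = species,
             fluorophore = fluorophore, day = as.character(day),
             brightness = brightness, method = method,
             condition = condition)
}

#' Per-day monomer reference brightness
#'
#' Arithmetic mean brightness over the monomer cells of a single day,
#' condition and method; the reference every dimer cell of that day is
#' ratioed against.
#'
#' @param records data.frame of monomer rows (see [brightness_record()])
#'   from one day.
#' @return The mean brightness; warns when fewer than 3 cells contribute.
#' @export
monomer_reference <- function(records) {
  if (!nrow(records)) stop("no monomer records")
  if (any(records$brightness <= 0)) stop("brightness must be > 0")
  if (length(unique(records$day)) > 1)
    stop("monomer_reference mixes days: ",
         paste(unique(records$day), collapse = ", "),
         "; reference per day")
  if (nrow(records) < 3)
    warning("monomer reference from fewer than 3 cells")
  mean(records$brightness)
}

#' Fluorescence probability from one dimer cell
#'
#' pf = B_dimer / B_monomer - 1, the apparent probability that a subunit
#' fluoresces, from a tandem-dimer cell's brightness and the same-day
#' monomer reference. Values outside \[0, 1\] (possible under noise) are
#' retained and flagged via the `"out_of_range"` attribute.
#'
#' @param dimer_brightness per-cell dimer brightness(es), > 0.
#' @param monomer_reference same-day monomer mean brightness, > 0.
#' @return Numeric pf value(s) with attribute `out_of_range`.
#' @export
pf_per_cell <- function(dimer_brightness, monomer_reference) {
  if (any(!is.finite(dimer_brightness)) || any(dimer_brightness <= 0))
    stop("dimer brightness must be > 0")
  if (!is.finite(monomer_reference) || monomer_reference <= 0)
    stop("monomer reference must be > 0")
  pf <- dimer_brightness / monomer_reference - 1
  attr(pf, "out_of_range") <- pf < 0 | pf > 1
  pf
}

#' Pool per-cell pf values
#'
#' Final pf estimate: mean over all per-cell values across sessions, with
#' SEM = SD / sqrt(n).
#'
#' @param pf_values numeric per-cell pf values (n >= 1).
#' @param sessions optional session id per value.
#' @return A list of class `pf_estimate`: `mean`, `sem` (NA with
#'   `sem_defined = FALSE` when n < 2), `n`, `sessions`, `values`,
#'   `n_out_of_range`.
#' @export
pool_pf <- function(pf_values, sessions = NULL) {
  pf_values <- as.numeric(pf_values)
  n <- length(pf_values)
  if (!n) stop("no pf values to pool")
  sem <- if (n >= 2) sd(pf_values) / sqrt(n) else NA_real_
  structure(list(mean = mean(pf_values), sem = sem,
                 sem_defined = n >= 2, n = n,
                 sessions = unique(sessions),
                 values = pf_values,
                 n_out_of_range = sum(pf_values < 0 | pf_values > 1)),
            class = "pf_estimate")
}

#' @export
print.pf_estimate <- function(x, ...) {
  cat(sprintf("<pf_estimate> pf = %.3f +/- %.3f (SEM), n = %d cells\n",
              x$mean, x$sem, x$n))
  invisible(x)
}

#' Full pf workflow over a brightness table
#'
#' For every (day, condition, method, fluorophore) group the monomer mean
#' is computed and each dimer cell is ratioed against it; the per-cell pf
#' values are then pooled per (fluorophore, condition, method) across days.
#'
#' @param records data.frame of [brightness_record()] rows, monomers and
#'   dimers.
#' @return A list: `per_cell` (data.frame with a pf per dimer cell) and
#'   `pooled` (data.frame: fluorophore, condition, method, pf_mean,
#'   pf_sem, n, n_days).
#' @export
pf_from_records <- function(records) {
  key <- interaction(records$day, records$condition, records$method,
                     records$fluorophore, drop = TRUE)
  per_cell <- do.call(rbind, lapply(split(records, key), function(g) {
    mono <- g[g$species == "monomer", ]
    dim_ <- g[g$species == "dimer", ]
    if (!nrow(mono) || !nrow(dim_)) return(NULL)
    ref <- monomer_reference(mono)
    data.frame(cell_id = dim_$cell_id, fluorophore = dim_$fluorophore,
               day = dim_$day, condition = dim_$condition,
               method = dim_$method,
               pf = as.numeric(pf_per_cell(dim_$brightness, ref)),
               monomer_reference = ref)
  }))
  if (is.null(per_cell)) stop("no day with both monomer and dimer cells")
  pool_key <- interaction(per_cell$fluorophore, per_cell$condition,
                          per_cell$method, drop = TRUE)
  pooled <- do.call(rbind, lapply(split(per_cell, pool_key), function(g) {
    est <- pool_pf(g$pf, sessions = g$day)
    data.frame(fluorophore = g$fluorophore[1], condition = g$condition[1],
               method = g$method[1], pf_mean = est$mean,
               pf_sem = est$sem, n = est$n,
               n_days = length(unique(g$day)))
  }))
  rownames(per_cell) <- rownames(pooled) <- NULL
  list(per_cell = per_cell, pooled = pooled)
}

#' Descriptive group summary
#'
#' The descriptive set reported under group plots: mean, median, SEM and
#' interquartile range (IQR = Q3 - Q1 with linear-interpolation quantiles),
#' plus the sample size.
#'
#' @param values numeric vector (n >= 1).
#' @return A list: `mean`, `median`, `sem` (NA when n < 2, with
#'   `sem_defined`), `iqr`, `q1`, `q3`, `n`.
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (!n) stop("empty group")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(mean = mean(values), median = median(values),
       sem = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
       sem_defined = n >= 2,
       iqr = q[2] - q[1], q1 = q[1], q3 = q[2], n = n)
}
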