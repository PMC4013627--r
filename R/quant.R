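## Per-scan reporter ratios, precursor grouping, aggregation, and
## internal-standard normalization.

#' Per-scan light:heavy reporter ratio with interference correction
#'
#' The raw ratio is light intensity over heavy intensity. The
#' \code{"n15"} correction removes the light reporter's natural one-15N
#' isotopologue, which lands exactly on the heavy reporter m/z:
#' \code{I_heavy_corrected = I_heavy - f15N * I_light} (f15N ~ 0.0073
#' from the computed fine structure). The \code{"c13"} correction
#' additionally subtracts the predicted Gaussian leakage of the light
#' 13C satellite (0.0063 Da above the heavy reporter) into the heavy
#' centroid at the scan's resolution setting; at 120,000 and above this
#' term is negligible.
#'
#' @param light,heavy Reporter channel intensities (vectorized).
#' @param corrections Character vector, subset of \code{c("n15", "c13")};
#'   empty for the raw ratio.
#' @param resolution FWHM resolution used for the c13 leakage model.
#' @param epsilon Floor for the corrected heavy intensity: values at or
#'   below \code{epsilon} flag the scan invalid (\code{NA} returned).
#' @return Numeric ratio(s); \code{NA} where a channel is absent or the
#'   corrected heavy intensity is non-positive.
#' @examples
#' per_scan_ratio(250, 1000, corrections = character(0))  # 0.25
#' per_scan_ratio(1000, 1000)                             # ~1.0074
#' @export
per_scan_ratio <- function(light, heavy, corrections = "n15",
                           resolution = 120000, epsilon = 0) {
  stopifnot(all(corrections %in% c("n15", "c13")))
  intf <- reporter_interference_fractions()
  hc <- heavy
  if ("n15" %in% corrections) hc <- hc - intf$f15N * light
  if ("c13" %in% corrections) {
    fw <- reporter_mz()[["heavy"]] / resolution
    leak <- exp(-4 * log(2) * intf$delta13C15N^2 / fw^2)
    hc <- hc - intf$f13C * leak * light
  }
  out <- light / hc
  out[is.na(light) | is.na(heavy) | hc <= epsilon] <- NA_real_
  out
}

## Cluster distance helper: precursor m/z distance modulo the heavy-light
## spacing (0.9970349/z) and the 13C isotope spacing (1.0033548/z), so
## that selections of the light mono, its isotope peaks, and the heavy
## partner all collapse onto one nitropeptide group.
.nq_aligned_dist <- function(a, b, z) {
  if (is.na(z) || z < 1) z <- 1
  shifts <- outer(-2:2 * (DELTA_N15 / z), -2:2 * (DELTA_C13 / z), `+`)
  min(abs(a - b - as.numeric(shifts)))
}

#' Group reporter hits and aggregate per-scan ratios
#'
#' Hits are clustered by precursor m/z — after aligning light/heavy
#' precursors by the 0.9970349/z offset (and isotope-peak selections by
#' the 13C spacing) — and retention-time contiguity. Within each cluster
#' the valid per-scan ratios are averaged (unweighted by default, which
#' matches reporting scan-to-scan mean and SD; intensity weighting
#' available).
#'
#' @param hits A \code{reporter_hits} data frame from one run.
#' @param corrections Passed to [per_scan_ratio()].
#' @param precursor_tol_ppm Precursor clustering tolerance after offset
#'   alignment, ppm.
#' @param rt_gap Maximum retention-time gap (minutes) between consecutive
#'   scans of one cluster.
#' @param weighted Intensity-weighted mean (weights = heavy intensity)
#'   instead of the unweighted scan mean.
#' @param resolution,epsilon Passed to [per_scan_ratio()].
#' @return A \code{ratio_results} data frame: one row per group with
#'   \code{group}, \code{precursor_mz}, \code{rt_center}, \code{n}
#'   (valid scans), \code{n_heavy_only}, \code{mean}, \code{sd}
#'   (sample SD, \code{NA} for n < 2), \code{corrections}.
#' @export
group_and_aggregate <- function(hits, corrections = "n15",
                                precursor_tol_ppm = 10, rt_gap = 0.5,
                                weighted = FALSE, resolution = 120000,
                                epsilon = 0) {
  hits <- as.data.frame(hits)
  if (!nrow(hits)) {
    return(structure(data.frame(group = integer(0), precursor_mz = numeric(0),
                                charge = integer(0),
                                rt_center = numeric(0), n = integer(0),
                                n_heavy_only = integer(0), mean = numeric(0),
                                sd = numeric(0), corrections = character(0)),
                     class = c("ratio_results", "data.frame")))
  }
  o <- order(hits$precursor_mz, hits$rt)
  hits <- hits[o, , drop = FALSE]
  # greedy single-link clustering along the sorted precursor axis
  cl <- integer(nrow(hits))
  reps <- list()
  for (i in seq_len(nrow(hits))) {
    assigned <- FALSE
    for (g in seq_along(reps)) {
      r <- reps[[g]]
      tol <- precursor_tol_ppm * 1e-6 * r$mz
      if (.nq_aligned_dist(hits$precursor_mz[i], r$mz, hits$charge[i]) <= tol &&
          hits$rt[i] >= r$rt_lo - rt_gap && hits$rt[i] <= r$rt_hi + rt_gap) {
        cl[i] <- g
        reps[[g]]$rt_lo <- min(r$rt_lo, hits$rt[i])
        reps[[g]]$rt_hi <- max(r$rt_hi, hits$rt[i])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      cl[i] <- length(reps) + 1L
      reps[[length(reps) + 1L]] <- list(mz = hits$precursor_mz[i],
                                        rt_lo = hits$rt[i],
                                        rt_hi = hits$rt[i])
    }
  }
  hits$ratio <- per_scan_ratio(hits$light_intensity, hits$heavy_intensity,
                               corrections = corrections,
                               resolution = resolution, epsilon = epsilon)
  rows <- lapply(sort(unique(cl)), function(g) {
    h <- hits[cl == g, , drop = FALSE]
    valid <- !is.na(h$ratio)
    r <- h$ratio[valid]
    m <- if (!length(r)) NA_real_
    else if (weighted) stats::weighted.mean(r, h$heavy_intensity[valid])
    else mean(r)
    zz <- h$charge[!is.na(h$charge)]
    data.frame(group = g,
               # lightest selected precursor: stays on the isotope grid, so
               # cross-run group matching by offset alignment works
               precursor_mz = min(h$precursor_mz),
               charge = if (length(zz)) as.integer(names(which.max(
                 table(zz)))) else NA_integer_,
               rt_center = stats::median(h$rt),
               n = sum(valid),
               n_heavy_only = sum(is.na(h$light_intensity) &
                                    !is.na(h$heavy_intensity)),
               mean = m,
               sd = if (length(r) >= 2) stats::sd(r) else NA_real_,
               corrections = paste(corrections, collapse = "+"))
  })
  structure(do.call(rbind, rows), class = c("ratio_results", "data.frame"))
}

#' Internal-standard normalization of a ratio against the reference
#'
#' The spiked heavy standard cancels between conditions:
#' \code{normalized = condition_mean / reference_mean}, i.e.
#' (condition/internal standard) / (reference/internal standard). The SD
#' is propagated to first order from both (independent) SDs:
#' \code{sd_norm = normalized * sqrt((sd_c/mean_c)^2 + (sd_r/mean_r)^2)}.
#'
#' @param condition,reference Single rows of a \code{ratio_results} frame
#'   (or lists with \code{mean}/\code{sd} fields).
#' @return List with \code{normalized}, \code{sd}, plus the inputs'
#'   means.
#' @examples
#' normalize_ratio(list(mean = 0.16, sd = 0.01), list(mean = 0.69, sd = 0.02))
#' @export
normalize_ratio <- function(condition, reference) {
  mc <- condition$mean; mr <- reference$mean
  sc <- condition$sd; sr <- reference$sd
  if (is.na(mr) || mr <= 0) stop("reference mean ratio must be positive")
  norm <- mc / mr
  relvar <- 0
  if (!is.null(sc) && !is.na(sc)) relvar <- relvar + (sc / mc)^2
  if (!is.null(sr) && !is.na(sr)) relvar <- relvar + (sr / mr)^2
  list(normalized = norm, sd = norm * sqrt(relvar),
       condition_mean = mc, reference_mean = mr)
}
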