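## Reporter-pair detection and diagnostic-ion chromatograms. The screen
## mirrors the high-mass-accuracy filtering idea: an MS/MS scan is a
## nitropeptide candidate when a peak matches the heavy (and/or light)
## nitrotyrosine reporter m/z within a few ppm, a window narrow enough to
## reject the light reporter's 13C satellite 0.0063 Da (~35 ppm) away.

#' Match the nitrotyrosine reporter pair in one MS/MS scan
#'
#' For each reporter target (light 181.0608, heavy 182.0578) the most
#' intense peak within the ppm tolerance is matched (ties broken by
#' smaller absolute ppm error). Returns \code{NULL} when neither target
#' matches; otherwise a one-row data frame reporting each channel
#' (\code{NA} for an absent channel).
#'
#' @param spectrum An \code{ms_spectrum} (centroided MS2 scan).
#' @param tol_ppm Matching tolerance in ppm (default 10).
#' @return One-row data frame with columns \code{scan_id}, \code{rt},
#'   \code{precursor_mz}, \code{charge}, \code{light_mz},
#'   \code{light_intensity}, \code{light_ppm}, \code{heavy_mz},
#'   \code{heavy_intensity}, \code{heavy_ppm}; or \code{NULL}.
#' @export
find_reporter_pair <- function(spectrum, tol_ppm = 10) {
  if (tol_ppm <= 0) stop("tolerance must be positive")
  targets <- reporter_mz()
  match1 <- function(target) {
    if (!length(spectrum$mz)) return(NULL)
    ppm <- (spectrum$mz - target) / target * 1e6
    cand <- which(abs(ppm) <= tol_ppm)
    if (!length(cand)) return(NULL)
    best <- cand[order(-spectrum$intensity[cand], abs(ppm[cand]))][1]
    list(mz = spectrum$mz[best], intensity = spectrum$intensity[best],
         ppm = ppm[best])
  }
  l <- match1(targets[["light"]])
  h <- match1(targets[["heavy"]])
  if (is.null(l) && is.null(h)) return(NULL)
  pre <- spectrum$precursor
  data.frame(
    scan_id = spectrum$id, rt = spectrum$rt,
    precursor_mz = if (!is.null(pre)) pre$mz else NA_real_,
    charge = if (!is.null(pre) && !is.null(pre$charge))
      as.integer(pre$charge) else NA_integer_,
    light_mz = if (is.null(l)) NA_real_ else l$mz,
    light_intensity = if (is.null(l)) NA_real_ else l$intensity,
    light_ppm = if (is.null(l)) NA_real_ else l$ppm,
    heavy_mz = if (is.null(h)) NA_real_ else h$mz,
    heavy_intensity = if (is.null(h)) NA_real_ else h$intensity,
    heavy_ppm = if (is.null(h)) NA_real_ else h$ppm,
    stringsAsFactors = FALSE)
}

#' Screen a whole run for reporter hits
#'
#' Applies [find_reporter_pair()] to every MS2 scan of a run.
#'
#' @param run An \code{ms_run}.
#' @param tol_ppm Matching tolerance, ppm.
#' @return Data frame of hits (zero rows if none), class
#'   \code{reporter_hits}.
#' @export
detect_reporters <- function(run, tol_ppm = 10) {
  hits <- lapply(ms2_scans(run), find_reporter_pair, tol_ppm = tol_ppm)
  hits <- hits[!vapply(hits, is.null, logical(1))]
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(scan_id = character(0), rt = numeric(0),
               precursor_mz = numeric(0), charge = integer(0),
               light_mz = numeric(0), light_intensity = numeric(0),
               light_ppm = numeric(0), heavy_mz = numeric(0),
               heavy_intensity = numeric(0), heavy_ppm = numeric(0),
               stringsAsFactors = FALSE)
  structure(out, class = c("reporter_hits", "data.frame"),
            tol_ppm = tol_ppm)
}

#' Diagnostic-ion (reconstructed) chromatogram
#'
#' One point per MS2 scan: the summed intensity of peaks inside
#' \code{[center - half_width, center + half_width]} (zero when none).
#' Run at half width 1.0 this reproduces the crowded nominal-mass trace;
#' at 0.001 Da only scans truly containing the reporter survive.
#'
#' @param run An \code{ms_run}.
#' @param center Window center, m/z (default the heavy reporter).
#' @param half_width Half width in Da (default 0.001).
#' @return Data frame with columns \code{scan_id}, \code{rt},
#'   \code{intensity}, in RT order.
#' @export
diagnostic_chromatogram <- function(run, center = reporter_mz()[["heavy"]],
                                    half_width = 0.001) {
  if (half_width <= 0) stop("half_width must be positive")
  sp <- ms2_scans(run)
  out <- data.frame(
    scan_id = vapply(sp, `[[`, character(1), "id"),
    rt = vapply(sp, `[[`, numeric(1), "rt"),
    intensity = vapply(sp, function(s) {
      sel <- s$mz >= center - half_width & s$mz <= center + half_width
      sum(s$intensity[sel])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  out[order(out$rt), , drop = FALSE]
}
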