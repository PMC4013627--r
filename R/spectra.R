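#' Centroided spectrum model
#'
#' The pipeline's in-memory scan currency: a centroided spectrum with
#' scan id, MS level, retention time in minutes, parallel m/z (strictly
#' ascending) and intensity arrays, and, for MS2 scans, precursor
#' metadata (selected m/z, charge possibly absent, isolation window
#' center and full width).
#'
#' @param id Native scan id string.
#' @param ms_level 1 or 2.
#' @param rt Retention time, minutes.
#' @param mz,intensity Parallel peak arrays.
#' @param precursor For MS2: \code{list(mz=, charge=, iso_center=,
#'   iso_width=)}; charge may be \code{NA}.
#' @param resolution Nominal resolution setting (optional).
#' @return An \code{ms_spectrum} object.
#' @export
ms_spectrum <- function(id, ms_level, rt, mz, intensity, precursor = NULL,
                        resolution = NA_real_) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  stopifnot(length(mz) == length(intensity),
            ms_level %in% c(1L, 2L),
            all(is.finite(intensity)), all(intensity >= 0))
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("spectrum m/z values must be strictly ascending (scan ", id, ")")
  if (!is.null(precursor)) {
    if (!is.null(precursor$iso_width) && !is.na(precursor$iso_width) &&
        precursor$iso_width <= 0)
      stop("isolation width must be positive (scan ", id, ")")
  }
  structure(list(id = as.character(id), ms_level = as.integer(ms_level),
                 rt = as.numeric(rt), mz = mz, intensity = intensity,
                 precursor = precursor, resolution = resolution),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s MS%d rt=%.3f min, %d peaks", x$id,
              x$ms_level, x$rt, length(x$mz)))
  if (!is.null(x$precursor))
    cat(sprintf(", precursor m/z %.4f", x$precursor$mz))
  cat("\n")
  invisible(x)
}

#' LC-MS/MS run container
#'
#' An ordered list of spectra (non-decreasing retention time), the source
#' path, and free-text instrument metadata.
#'
#' @param spectra List of \code{ms_spectrum}.
#' @param source Source path or label.
#' @param metadata Free-text instrument/run description.
#' @return An \code{ms_run} object.
#' @export
ms_run <- function(spectra = list(), source = NA_character_,
                   metadata = NA_character_) {
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (length(rts) > 1 && any(diff(rts) < 0))
    stop("run spectra must be in non-decreasing retention-time order")
  structure(list(spectra = spectra, source = source, metadata = metadata),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat(sprintf("<ms_run> %d spectra (%d MS1, %d MS2)", length(lv),
              sum(lv == 1L), sum(lv == 2L)))
  if (!is.na(x$source)) cat(" from", x$source)
  cat("\n")
  invisible(x)
}

#' @export
length.ms_run <- function(x) length(x$spectra)

#' MS2 scans of a run
#'
#' @param run An \code{ms_run}.
#' @return List of the run's MS2 spectra in retention-time order.
#' @export
ms2_scans <- function(run) {
  lv <- vapply(run$spectra, `[[`, integer(1), "ms_level")
  sp <- run$spectra[lv == 2L]
  sp[order(vapply(sp, `[[`, numeric(1), "rt"))]
}
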