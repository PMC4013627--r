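## mzML reading/writing via the mzR/proteowizard backend. Retention times
## are seconds on disk (mzML convention) and minutes in memory (the unit
## all chromatograms here are expressed in).

#' Read an mzML file into a run
#'
#' Loads all spectra from an mzML file into the package's in-memory scan
#' model. Retention times are converted to minutes; a missing precursor
#' charge is preserved as \code{NA}; profile-mode spectra are centroided
#' by local-maximum apex picking with 3-point parabolic m/z refinement
#' (flagged via a message) since the pipeline operates on centroids.
#'
#' @param path Path to an mzML file.
#' @param centroid_profile Centroid profile-mode spectra on load
#'   (default TRUE).
#' @return An \code{ms_run}.
#' @export
read_mzml <- function(path, centroid_profile = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  h <- NULL
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop("cannot open mzML '", path,
                                              "': ", conditionMessage(e)))
  on.exit(mzR::close(handle), add = TRUE)
  n <- length(handle)
  meta <- tryCatch({
    ii <- mzR::instrumentInfo(handle)
    paste(unlist(ii[nzchar(unlist(ii))]), collapse = "; ")
  }, error = function(e) NA_character_)
  if (n == 0) return(ms_run(list(), source = path, metadata = meta))
  h <- mzR::header(handle)
  pk <- mzR::peaks(handle)
  if (n == 1 && is.matrix(pk)) pk <- list(pk)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pk[[i]]
    mzv <- p[, 1]; inten <- p[, 2]
    centroided <- isTRUE(h$centroided[i])
    if (!centroided && length(mzv) && centroid_profile) {
      cp <- .nq_centroid(mzv, inten)
      mzv <- cp$mz; inten <- cp$intensity
    }
    prec <- NULL
    if (h$msLevel[i] >= 2L) {
      ch <- h$precursorCharge[i]
      width <- h$isolationWindowLowerOffset[i] + h$isolationWindowUpperOffset[i]
      prec <- list(
        mz = h$precursorMZ[i],
        charge = if (is.na(ch) || ch == 0) NA_integer_ else as.integer(ch),
        iso_center = h$isolationWindowTargetMZ[i],
        iso_width = width)
    }
    spectra[[i]] <- ms_spectrum(
      id = h$spectrumId[i], ms_level = h$msLevel[i],
      rt = h$retentionTime[i] / 60, mz = mzv, intensity = inten,
      precursor = prec)
  }
  o <- order(vapply(spectra, `[[`, numeric(1), "rt"))
  ms_run(spectra[o], source = path, metadata = meta)
}

## Local-maximum apex picking with 3-point parabolic m/z refinement.
.nq_centroid <- function(mz, intensity) {
  n <- length(mz)
  if (n < 3) return(list(mz = mz, intensity = intensity))
  apex <- which(intensity[2:(n - 1)] > intensity[1:(n - 2)] &
                  intensity[2:(n - 1)] >= intensity[3:n]) + 1L
  apex <- apex[intensity[apex] > 0]
  refined <- vapply(apex, function(i) {
    y1 <- intensity[i - 1]; y2 <- intensity[i]; y3 <- intensity[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den == 0) return(mz[i])
    d <- 0.5 * (y1 - y3) / den
    mz[i] + d * (mz[i + 1] - mz[i - 1]) / 2
  }, numeric(1))
  list(mz = refined, intensity = intensity[apex])
}

#' Write a run to mzML
#'
#' Writes a standards-conformant, indexed, centroid-annotated mzML 1.1
#' file that round-trips through [read_mzml()] (scan counts, MS levels,
#' retention times, peak arrays and precursor fields preserved). The
#' run's free-text \code{metadata} field is an in-memory annotation only;
#' the writer backend does not serialize it.
#'
#' @param run An \code{ms_run}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  n <- length(run$spectra)
  if (n == 0) {
    # mzR cannot write a zero-spectrum file; emit a minimal empty mzML
    writeLines(.nq_empty_mzml(), path)
    return(invisible(path))
  }
  pk <- vector("list", n)
  na_i <- rep(NA_integer_, n); na_r <- rep(NA_real_, n)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = na_i, polarity = rep(1L, n), peaksCount = na_i,
    totIonCurrent = na_r, retentionTime = na_r,
    basePeakMZ = na_r, basePeakIntensity = na_r,
    collisionEnergy = na_r, ionisationEnergy = rep(0, n),
    lowMZ = na_r, highMZ = na_r,
    precursorScanNum = na_i, precursorMZ = na_r,
    precursorCharge = na_i, precursorIntensity = na_r,
    mergedScan = na_i, mergedResultScanNum = na_i,
    mergedResultStartScanNum = na_i, mergedResultEndScanNum = na_i,
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = rep(NA_character_, n), centroided = rep(TRUE, n),
    ionMobilityDriftTime = na_r,
    isolationWindowTargetMZ = na_r, isolationWindowLowerOffset = na_r,
    isolationWindowUpperOffset = na_r,
    scanWindowLowerLimit = na_r, scanWindowUpperLimit = na_r,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- run$spectra[[i]]
    pk[[i]] <- cbind(mz = s$mz, intensity = s$intensity)
    hdr$msLevel[i] <- s$ms_level
    hdr$peaksCount[i] <- length(s$mz)
    hdr$totIonCurrent[i] <- sum(s$intensity)
    hdr$retentionTime[i] <- s$rt * 60
    if (length(s$mz)) {
      bp <- which.max(s$intensity)
      hdr$basePeakMZ[i] <- s$mz[bp]
      hdr$basePeakIntensity[i] <- s$intensity[bp]
      hdr$lowMZ[i] <- min(s$mz); hdr$highMZ[i] <- max(s$mz)
    } else {
      hdr$lowMZ[i] <- 0; hdr$highMZ[i] <- 0
      hdr$basePeakMZ[i] <- 0; hdr$basePeakIntensity[i] <- 0
    }
    hdr$spectrumId[i] <- s$id
    if (!is.null(s$precursor)) {
      hdr$precursorMZ[i] <- s$precursor$mz
      if (!is.null(s$precursor$charge) && !is.na(s$precursor$charge))
        hdr$precursorCharge[i] <- as.integer(s$precursor$charge)
      if (!is.null(s$precursor$iso_center) && !is.na(s$precursor$iso_center)) {
        hdr$isolationWindowTargetMZ[i] <- s$precursor$iso_center
        hdr$isolationWindowLowerOffset[i] <- s$precursor$iso_width / 2
        hdr$isolationWindowUpperOffset[i] <- s$precursor$iso_width / 2
      }
      hdr$precursorIntensity[i] <- 0
    }
  }
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

.nq_empty_mzml <- function() {
  c('<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" id="empty" version="1.1.0">',
    '  <cvList count="2">',
    paste0('    <cv id="MS" fullName="Proteomics Standards Initiative ',
           'Mass Spectrometry Ontology" version="4.1.0" URI=',
           '"https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>'),
    paste0('    <cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI=',
           '"https://raw.githubusercontent.com/bio-ontology-research-group/',
           'unit-ontology/master/unit.obo"/>'),
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '    </fileContent>',
    '  </fileDescription>',
    '  <softwareList count="1">',
    '    <software id="sw" version="0.1.0">',
    paste0('      <cvParam cvRef="MS" accession="MS:1000799" ',
           'name="custom unreleased software tool" value="nitroquant"/>'),
    '    </software>',
    '  </softwareList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1">',
    '      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '    </instrumentConfiguration>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="dp">',
    '      <processingMethod order="0" softwareRef="sw">',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '      </processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    '  <run id="run" defaultInstrumentConfigurationRef="IC1">',
    '    <spectrumList count="0" defaultDataProcessingRef="dp">',
    '    </spectrumList>',
    '  </run>',
    '</mzML>')
}
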