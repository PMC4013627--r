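## Seeded simulator of data-dependent acquisition (DDA) runs containing
## co-isolated light/heavy nitropeptide pairs, emulating the acquisition
## used for the spike-in experiments: survey scans over a fixed m/z
## range, MS/MS on the top-N most abundant precursor peaks with a wide
## isolation window so that a light/heavy pair (spaced 0.9970349/z) is
## always co-isolated, and dynamic exclusion after one repeat.

#' Define a simulated eluting species
#'
#' @param pep A \code{peptide} (or notation string), e.g. a nitropeptide
#'   carrying \code{nitro_light} or \code{nitro_heavy}.
#' @param charge Precursor charge state.
#' @param abundance Relative abundance (arbitrary intensity units at the
#'   elution apex).
#' @param rt_center Elution apex, minutes.
#' @param rt_sigma Gaussian elution sigma, minutes.
#' @param id Species label (defaults to the peptide notation).
#' @return A \code{sim_species} object.
#' @export
sim_species <- function(pep, charge, abundance, rt_center, rt_sigma = 0.08,
                        id = NULL) {
  if (is.character(pep)) {
    if (is.null(id)) id <- pep
    pep <- parse_peptide(pep)
  }
  stopifnot(abundance > 0, rt_sigma > 0, charge >= 1)
  if (is.null(id)) id <- pep$sequence
  structure(list(pep = pep, charge = as.integer(charge),
                 abundance = abundance, rt_center = rt_center,
                 rt_sigma = rt_sigma, id = id),
            class = "sim_species")
}

#' DDA acquisition settings for the simulator
#'
#' Defaults follow the acquisition the pipeline targets: survey scans
#' m/z 400-2000, MS/MS on the top three most abundant ions with an
#' isolation width of 5, dynamic exclusion 30 s after one repeat count,
#' 240,000 survey / 120,000 MS2 resolution.
#'
#' @param mz_range Survey scan range, m/z.
#' @param topN Precursors fragmented per cycle.
#' @param isolation_width Full isolation window width, m/z.
#' @param dynamic_exclusion Exclusion time, seconds.
#' @param repeat_count Selections allowed before exclusion kicks in.
#' @param cycle_time Seconds per survey cycle.
#' @param run_length Run length, minutes.
#' @param ms1_resolution,ms2_resolution Nominal resolution settings.
#' @param min_intensity MS1 peak intensity floor for precursor selection.
#' @return An \code{acq_config} object.
#' @export
acq_config <- function(mz_range = c(400, 2000), topN = 3,
                       isolation_width = 5, dynamic_exclusion = 30,
                       repeat_count = 1, cycle_time = 2, run_length = 5,
                       ms1_resolution = 240000, ms2_resolution = 120000,
                       min_intensity = 1) {
  stopifnot(topN >= 1, isolation_width > 0, cycle_time > 0, run_length > 0)
  structure(list(mz_range = mz_range, topN = as.integer(topN),
                 isolation_width = isolation_width,
                 dynamic_exclusion = dynamic_exclusion,
                 repeat_count = as.integer(repeat_count),
                 cycle_time = cycle_time, run_length = run_length,
                 ms1_resolution = ms1_resolution,
                 ms2_resolution = ms2_resolution,
                 min_intensity = min_intensity),
            class = "acq_config")
}

#' Noise model for simulated runs
#'
#' @param background_peaks Background peak count per MS2 scan (uniform in
#'   m/z over 100 to the precursor m/z, by default excluding a guard band
#'   of 0.02 m/z around both reporter ions; \code{adversarial = TRUE}
#'   instead plants decoy peaks 0.01-0.05 m/z from the reporters to
#'   exercise tolerance logic).
#' @param background_mean Mean background peak intensity (exponential).
#' @param mz_jitter_ppm Gaussian m/z jitter sigma, ppm.
#' @param intensity_sigma Multiplicative (log-normal) intensity noise
#'   sigma.
#' @param adversarial Plant near-reporter decoys (see above).
#' @return A \code{noise_model} object.
#' @export
noise_model <- function(background_peaks = 30, background_mean = 20,
                        mz_jitter_ppm = 2, intensity_sigma = 0.05,
                        adversarial = FALSE) {
  stopifnot(mz_jitter_ppm >= 0, intensity_sigma >= 0, background_peaks >= 0)
  structure(list(background_peaks = as.integer(background_peaks),
                 background_mean = background_mean,
                 mz_jitter_ppm = mz_jitter_ppm,
                 intensity_sigma = intensity_sigma,
                 adversarial = isTRUE(adversarial)),
            class = "noise_model")
}

#' Noise-free model (for construction-exact tests)
#' @return A \code{noise_model} with all noise terms zero.
#' @export
noise_off <- function() noise_model(background_peaks = 0, mz_jitter_ppm = 0,
                                    intensity_sigma = 0)

## Precompute per-species stick lists used by the scheduler.
.nq_species_sticks <- function(sp, immonium_yield) {
  comp <- peptide_composition(sp$pep)
  fs <- fine_structure(comp, prune_below = 1e-4)
  # aggregate fine structure into the first three nominal isotope clusters
  mono <- fs$mass[1]
  cl <- round(fs$mass - mono)
  keep <- cl <= 2
  ab <- rowsum(fs$abundance[keep], cl[keep])
  mzv <- rowsum(fs$mass[keep] * fs$abundance[keep], cl[keep]) / ab
  prec <- data.frame(mz = mz(mzv[, 1], sp$charge),
                     rel = ab[, 1] / max(ab[, 1]))

  fr <- fragment_ions(sp$pep, series = c("b", "y"), max_charge = 1L)
  frag <- data.frame(mz = fr$mz, rel = 1.0)
  nitro <- vapply(sp$pep$mods, function(m)
    m$mod$name %in% c("nitro_light", "nitro_heavy"), logical(1))
  reporter <- NULL
  if (any(nitro)) {
    m <- sp$pep$mods[nitro][[1]]
    ion <- immonium_ion("Y", m$mod$name)
    kind <- if (m$mod$name == "nitro_light") "light" else "heavy"
    intf <- reporter_interference_fractions()
    # reporter stick plus its natural A+1 fine-structure satellites: for
    # the light reporter the one-15N species lands exactly on the heavy
    # reporter m/z and the one-13C species 0.0063 above it
    reporter <- data.frame(
      mz = c(ion$mz, ion$mz + DELTA_N15, ion$mz + DELTA_C13),
      rel = c(1, intf$f15N, intf$f13C) * immonium_yield,
      channel = c(kind, "satellite", "satellite"))
  }
  list(precursor = prec, frag = frag, reporter = reporter,
       reporter_channel = if (is.null(reporter)) NA_character_
                          else reporter$channel[1])
}

#' Generate a simulated DDA run
#'
#' MS1 scans contain each species' first three precursor isotope peaks
#' scaled by a Gaussian elution profile; a top-N scheduler with dynamic
#' exclusion picks precursor peaks per cycle; each MS2 scan sums the b/y
#' fragment and reporter-ion sticks of every species whose precursor
#' monoisotopic m/z lies inside the isolation window (so a light/heavy
#' pair always co-fragments at the default width of 5); reporter
#' intensities are proportional to species abundances; noise is applied
#' last. The light reporter's natural one-15N isotopologue is planted at
#' exactly the heavy reporter m/z, so the heavy channel carries the same
#' isotopic interference real data would.
#'
#' @param species List of [sim_species()].
#' @param acq An [acq_config()].
#' @param noise A [noise_model()].
#' @param seed Integer seed fixing all random draws.
#' @param immonium_yield Reporter intensity relative to the flat b/y
#'   fragment base intensity.
#' @return List with \code{run} (an \code{ms_run}) and \code{manifest}
#'   (data frame: one row per MS2 scan with scan id, RT, isolation
#'   center, contributing species ids, true light/heavy reporter
#'   intensities and true ratio).
#' @export
generate_run <- function(species, acq = acq_config(), noise = noise_model(),
                         seed = 1, immonium_yield = 3) {
  stopifnot(length(species) >= 1)
  if (!is.null(get0(".Random.seed", envir = globalenv()))) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  for (sp in species) {
    if (sp$rt_center < 0 || sp$rt_center > acq$run_length)
      stop("species '", sp$id, "' elutes outside the run length")
  }
  pre <- lapply(species, .nq_species_sticks, immonium_yield = immonium_yield)
  rmz <- reporter_mz()
  cyc <- seq(0, acq$run_length * 60 - acq$cycle_time, by = acq$cycle_time)
  spectra <- list(); manifest <- list()
  scan_n <- 0L
  excl <- data.frame(mz = numeric(0), until = numeric(0), count = integer(0))
  jit <- function(m) if (noise$mz_jitter_ppm > 0)
    m * (1 + stats::rnorm(length(m), 0, noise$mz_jitter_ppm * 1e-6)) else m
  amp <- function(x) if (noise$intensity_sigma > 0)
    x * exp(stats::rnorm(length(x), 0, noise$intensity_sigma)) else x
  for (t in cyc) {
    rt_min <- t / 60
    elu <- vapply(species, function(sp)
      sp$abundance * exp(-(rt_min - sp$rt_center)^2 / (2 * sp$rt_sigma^2)),
      numeric(1))
    # --- MS1 scan
    mzs <- numeric(0); ints <- numeric(0); owner <- integer(0)
    for (i in seq_along(species)) {
      p <- pre[[i]]$precursor
      keep <- p$mz >= acq$mz_range[1] & p$mz <= acq$mz_range[2]
      mzs <- c(mzs, p$mz[keep]); ints <- c(ints, p$rel[keep] * elu[i])
      owner <- c(owner, rep(i, sum(keep)))
    }
    vis <- ints >= acq$min_intensity
    mzs <- mzs[vis]; ints <- ints[vis]; owner <- owner[vis]
    scan_n <- scan_n + 1L
    o <- order(mzs)
    ms1_mz <- jit(mzs[o]); ms1_i <- amp(ints[o])
    oo <- order(ms1_mz)
    spectra[[length(spectra) + 1L]] <- ms_spectrum(
      id = paste0("scan=", scan_n), ms_level = 1L, rt = rt_min,
      mz = ms1_mz[oo], intensity = ms1_i[oo],
      resolution = acq$ms1_resolution)
    if (!length(mzs)) next
    # --- DDA selection on true (pre-noise) MS1 peaks
    excl <- excl[excl$until > t | excl$count <= acq$repeat_count, , drop = FALSE]
    cand <- order(-ints)
    picked <- 0L
    for (ci in cand) {
      if (picked >= acq$topN) break
      pmz <- mzs[ci]
      hit <- which(abs(excl$mz - pmz) < 0.01)
      if (length(hit)) {
        if (excl$count[hit[1]] > acq$repeat_count && excl$until[hit[1]] > t)
          next
        excl$count[hit[1]] <- excl$count[hit[1]] + 1L
        excl$until[hit[1]] <- t + acq$dynamic_exclusion
      } else {
        excl <- rbind(excl, data.frame(mz = pmz, until = t + acq$dynamic_exclusion,
                                       count = 1L))
      }
      picked <- picked + 1L
      scan_n <- scan_n + 1L
      rt2 <- rt_min + picked * acq$cycle_time / (acq$topN + 1) / 60
      lo <- pmz - acq$isolation_width / 2
      hi <- pmz + acq$isolation_width / 2
      contrib <- which(vapply(seq_along(species), function(i)
        elu[i] >= acq$min_intensity &&
          pre[[i]]$precursor$mz[1] >= lo && pre[[i]]$precursor$mz[1] <= hi,
        logical(1)))
      fmz <- numeric(0); fint <- numeric(0)
      true_light <- 0; true_heavy <- 0
      for (i in contrib) {
        fmz <- c(fmz, pre[[i]]$frag$mz)
        fint <- c(fint, pre[[i]]$frag$rel * elu[i])
        rep_st <- pre[[i]]$reporter
        if (!is.null(rep_st)) {
          fmz <- c(fmz, rep_st$mz)
          fint <- c(fint, rep_st$rel * elu[i])
          if (pre[[i]]$reporter_channel == "light")
            true_light <- true_light + rep_st$rel[1] * elu[i]
          else true_heavy <- true_heavy + rep_st$rel[1] * elu[i]
        }
      }
      # background noise peaks, avoiding (default) or crowding
      # (adversarial) the reporter region
      if (noise$background_peaks > 0) {
        bm <- stats::runif(noise$background_peaks, 100, max(500, pmz))
        guard <- outer(bm, rmz, function(a, b) abs(a - b)) < 0.02
        bm <- bm[!apply(guard, 1, any)]
        bi <- stats::rexp(length(bm), 1 / noise$background_mean)
        fmz <- c(fmz, bm); fint <- c(fint, bi)
        if (noise$adversarial) {
          dm <- stats::runif(4, 0.01, 0.05) * sample(c(-1, 1), 4, TRUE)
          fmz <- c(fmz, rmz[c(1, 1, 2, 2)] + dm)
          fint <- c(fint, stats::rexp(4, 1 / noise$background_mean))
        }
      }
      fmz <- jit(fmz); fint <- amp(fint)
      # merge coincident sticks (e.g. shared fragment m/z) into one centroid
      if (length(fmz)) {
        key <- round(fmz, 6)
        fint <- rowsum(fint, key, reorder = TRUE)[, 1]
        fmz <- sort(unique(key))
      }
      spectra[[length(spectra) + 1L]] <- ms_spectrum(
        id = paste0("scan=", scan_n), ms_level = 2L, rt = rt2,
        mz = fmz, intensity = fint,
        precursor = list(mz = pmz,
                         charge = if (length(contrib))
                           species[[contrib[1]]]$charge else NA_integer_,
                         iso_center = pmz, iso_width = acq$isolation_width),
        resolution = acq$ms2_resolution)
      manifest[[length(manifest) + 1L]] <- data.frame(
        scan_id = paste0("scan=", scan_n), rt = rt2, precursor_mz = pmz,
        species = paste(vapply(species[contrib], `[[`, character(1), "id"),
                        collapse = ";"),
        true_light = true_light, true_heavy = true_heavy,
        true_ratio = if (true_heavy > 0) true_light / true_heavy else NA_real_)
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest)
    else data.frame(scan_id = character(0), rt = numeric(0),
                    precursor_mz = numeric(0), species = character(0),
                    true_light = numeric(0), true_heavy = numeric(0),
                    true_ratio = numeric(0))
  run <- ms_run(spectra, source = sprintf("simulated(seed=%d)", seed),
                metadata = "nitroquant DDA simulator")
  list(run = run, manifest = manifest)
}

#' Spike-in mixing-ratio fixture
#'
#' Builds the simulated counterpart of the spike-in dilution design: five
#' DDA runs containing the two BSA nitropeptides YLYEIAR (nitrated Y1)
#' and YICDNQDTISSK (nitrated Y1, carbamidomethyl C3) as light/heavy
#' pairs — one 1:1 reference run, three 0.25:1 technical replicates with
#' different seeds, and one 0.10:1 run — plus unmodified background
#' peptides.
#'
#' @param seed Base seed; replicate runs use consecutive offsets.
#' @param noise A [noise_model()].
#' @param acq An [acq_config()].
#' @param background Include unmodified background species.
#' @return Named list of \code{list(run=, manifest=, ratio=)} entries:
#'   \code{ref} (1:1), \code{r025a/b/c} (0.25:1) and \code{r010} (0.10:1).
#' @export
table1_fixture <- function(seed = 1, noise = noise_model(),
                           acq = acq_config(), background = TRUE) {
  heavy_ab <- 1000
  build <- function(ratio, s) {
    sp <- list(
      sim_species("YLYEIAR 1:nitro_light", charge = 2,
                  abundance = ratio * heavy_ab, rt_center = 1.6,
                  id = "YLYEIAR_light"),
      sim_species("YLYEIAR 1:nitro_heavy", charge = 2,
                  abundance = heavy_ab, rt_center = 1.6,
                  id = "YLYEIAR_heavy"),
      sim_species("YICDNQDTISSK 1:nitro_light 3:cam", charge = 2,
                  abundance = ratio * heavy_ab, rt_center = 3.2,
                  id = "YICDNQDTISSK_light"),
      sim_species("YICDNQDTISSK 1:nitro_heavy 3:cam", charge = 2,
                  abundance = heavy_ab, rt_center = 3.2,
                  id = "YICDNQDTISSK_heavy"))
    if (background) {
      sp <- c(sp, list(
        sim_species("LVNELTEFAK", charge = 2, abundance = 2000,
                    rt_center = 0.9, id = "bg1"),
        sim_species("HLVDEPQNLIK", charge = 2, abundance = 1500,
                    rt_center = 2.4, id = "bg2"),
        sim_species("AEFVEVTK", charge = 1, abundance = 1200,
                    rt_center = 4.1, id = "bg3")))
    }
    out <- generate_run(sp, acq = acq, noise = noise, seed = s)
    out$ratio <- ratio
    out
  }
  seed <- as.integer(seed)
  list(ref = build(1, seed),
       r025a = build(0.25, seed + 1L),
       r025b = build(0.25, seed + 2L),
       r025c = build(0.25, seed + 3L),
       r010 = build(0.10, seed + 4L))
}
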