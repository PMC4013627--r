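## Isotope fine structure, Gaussian FWHM profile synthesis, and minimum
## resolution for near-isobaric doublets. The fine structure keeps
## isotopologue species mass-resolved (e.g. 13C vs 15N substitutions at
## nominal A+1, split by ~0.0063 Da), which is the whole point for the
## nitrotyrosine reporter pair: the heavy (15N-labeled) monoisotopic peak
## sits 0.0063 Da below the light reporter's 13C satellite.

## Merge species whose exact masses coincide (same isotopologue reached by
## a different expansion order). 1e-9 Da is far below any fine-structure
## split we care about.
.nq_merge_pattern <- function(mass, abundance, digits = 9) {
  key <- round(mass, digits)
  ab <- rowsum(abundance, key, reorder = TRUE)
  # abundance-weighted mean mass within each key (masses are essentially equal)
  wm <- rowsum(mass * abundance, key, reorder = TRUE) / ab
  o <- order(wm[, 1])
  list(mass = wm[o, 1], abundance = ab[o, 1])
}

## Exact per-element pattern: multinomial expansion over isotope count
## vectors for n atoms of one element.
.nq_element_pattern <- function(token, n, prune = 0) {
  tab <- .nq_catalog[[token]]
  k <- nrow(tab)
  if (k == 1 || n == 0) {
    return(list(mass = tab$mass[1] * n, abundance = 1))
  }
  # enumerate count vectors (n1,...,nk) summing to n, depth-first with
  # probability pruning (prune is relative to the running max term)
  masses <- numeric(0); probs <- numeric(0)
  counts <- integer(k)
  rec <- function(i, left, logp, massacc) {
    if (i == k) {
      lp <- logp + left * log(tab$abundance[k])
      masses[length(masses) + 1L] <<- massacc + left * tab$mass[k]
      probs[length(probs) + 1L] <<- exp(lp + lgamma(n + 1) -
        sum(lgamma(c(counts[seq_len(k - 1)], left) + 1)))
      return()
    }
    for (ni in 0:left) {
      counts[i] <<- ni
      rec(i + 1L, left - ni, logp + ni * log(tab$abundance[i]),
          massacc + ni * tab$mass[i])
    }
  }
  rec(1L, n, 0, 0)
  if (prune > 0) {
    keep <- probs >= prune * max(probs)
    masses <- masses[keep]; probs <- probs[keep]
  }
  .nq_merge_pattern(masses, probs)
}

.nq_convolve <- function(a, b, prune = 0) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$abundance, b$abundance)
  out <- .nq_merge_pattern(as.numeric(mass), as.numeric(ab))
  if (prune > 0) {
    keep <- out$abundance >= prune * max(out$abundance)
    out <- list(mass = out$mass[keep], abundance = out$abundance[keep])
  }
  out
}

#' Isotope fine structure of an elemental composition
#'
#' Exact multinomial expansion of the isotopologue distribution per
#' element, convolved across elements, keeping distinct exact masses
#' separate (fine structure, not nominal-mass aggregation). Fixed-isotope
#' pseudo-elements (e.g. the 15N of the heavy nitro group) contribute a
#' single mass. Species below \code{prune_below} of the base (most
#' abundant) peak are dropped and the remainder renormalized to sum to 1.
#'
#' @param comp An \code{elem_comp}, formula string, or named count vector.
#' @param prune_below Abundance threshold relative to the base peak
#'   (default 1e-6); 0 disables pruning (practical only for small
#'   compositions).
#' @return An \code{isotope_pattern}: data frame with columns \code{mass}
#'   (Da, ascending) and \code{abundance} (fractions summing to 1), with
#'   the provenance composition as attribute \code{"composition"}.
#' @examples
#' fine_structure("C1")                       # 12.000 / 13.0034 doublet
#' fs <- fine_structure("C8H9N2O3")           # light reporter cation
#' @export
fine_structure <- function(comp, prune_below = 1e-6) {
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- as_composition(comp)
  if (prune_below < 0 || prune_below >= 1)
    stop("prune_below must be in [0, 1)")
  # intermediate pruning far below the final threshold bounds growth for
  # large molecules without touching reported species
  ip <- if (prune_below > 0) prune_below * 1e-3 else 0
  pat <- list(mass = 0, abundance = 1)
  for (tok in names(comp)) {
    ep <- .nq_element_pattern(tok, comp[[tok]], prune = ip)
    pat <- .nq_convolve(pat, ep, prune = ip)
  }
  keep <- pat$abundance >= prune_below * max(pat$abundance)
  mass <- pat$mass[keep]
  ab <- pat$abundance[keep]
  ab <- ab / sum(ab)
  structure(data.frame(mass = unname(mass), abundance = unname(ab)),
            class = c("isotope_pattern", "data.frame"),
            composition = comp)
}

#' Peak shape model (Gaussian, FWHM resolution)
#'
#' Gaussian peaks with width set by FWHM resolution R = m/dm. Two
#' reference modes: \code{"at_peak"} takes R as holding at each peak's own
#' m/z (FWHM = m/R); \code{"orbitrap_sqrt"} models an Orbitrap-style
#' sqrt(m) falloff anchored at m/z 400 (the instrument convention behind a
#' setting like "240,000 at m/z 400"), FWHM = m / (R * sqrt(400/m)).
#'
#' @param resolution FWHM resolution, dimensionless.
#' @param mode \code{"at_peak"} (default) or \code{"orbitrap_sqrt"}.
#' @return A \code{peak_shape} object.
#' @export
peak_shape <- function(resolution, mode = c("at_peak", "orbitrap_sqrt")) {
  mode <- match.arg(mode)
  stopifnot(resolution > 0)
  structure(list(resolution = resolution, mode = mode), class = "peak_shape")
}

#' FWHM at a given m/z under a peak shape model
#' @param shape A \code{peak_shape}.
#' @param m m/z value(s).
#' @return FWHM in Da.
#' @export
fwhm_at <- function(shape, m) {
  switch(shape$mode,
         at_peak = m / shape$resolution,
         orbitrap_sqrt = m / (shape$resolution * sqrt(400 / m)))
}

#' Synthesize a Gaussian profile from stick peaks
#'
#' Sum of Gaussians, one per stick, centered at the stick m/z with height
#' proportional to its intensity and FWHM from the shape model; sampled on
#' a regular grid covering the sticks plus/minus 5 FWHM.
#'
#' @param sticks Data frame or two-column matrix of (m/z, intensity), or an
#'   \code{isotope_pattern}.
#' @param shape A \code{peak_shape} (or resolution number, taken as
#'   at-peak mode).
#' @param grid_step Sampling step in Da; default FWHM/50 at the lightest
#'   stick. Must be at most FWHM/10.
#' @return Data frame with columns \code{mz}, \code{intensity}.
#' @export
profile_spectrum <- function(sticks, shape, grid_step = NULL) {
  if (is.numeric(shape)) shape <- peak_shape(shape)
  sticks <- .nq_as_sticks(sticks)
  if (!nrow(sticks)) stop("empty stick list")
  fw <- fwhm_at(shape, sticks$mz)
  if (is.null(grid_step)) grid_step <- min(fw) / 50
  if (grid_step > min(fw) / 10)
    stop("grid_step must be at most min FWHM / 10 (", format(min(fw) / 10),
         ")")
  lo <- min(sticks$mz) - 5 * max(fw)
  hi <- max(sticks$mz) + 5 * max(fw)
  x <- seq(lo, hi, by = grid_step)
  y <- numeric(length(x))
  c4 <- 4 * log(2)
  for (i in seq_len(nrow(sticks))) {
    y <- y + sticks$intensity[i] * exp(-c4 * (x - sticks$mz[i])^2 / fw[i]^2)
  }
  data.frame(mz = x, intensity = y)
}

.nq_as_sticks <- function(x) {
  if (inherits(x, "isotope_pattern"))
    return(data.frame(mz = x$mass, intensity = x$abundance))
  x <- as.data.frame(x)
  names(x)[1:2] <- c("mz", "intensity")
  if (nrow(x)) {
    stopifnot(all(x$intensity > 0), !anyDuplicated(x$mz))
    x <- x[order(x$mz), , drop = FALSE]
  }
  x
}

## Local maxima of a sampled profile, ignoring numerically negligible ones.
.nq_local_maxima <- function(y, floor_frac = 1e-9) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i[y[i] > floor_frac * max(y)]
}

#' Separation criterion for a doublet profile
#'
#' @param kind \code{"two_maxima"} (two distinct local maxima) or
#'   \code{"valley"} (two maxima whose intervening minimum is at most
#'   \code{valley_fraction} of the smaller apex).
#' @param valley_fraction Fraction in (0, 1); default 0.10.
#' @return A \code{resolution_criterion} object.
#' @export
resolution_criterion <- function(kind = c("two_maxima", "valley"),
                                 valley_fraction = 0.10) {
  kind <- match.arg(kind)
  stopifnot(valley_fraction > 0, valley_fraction < 1)
  structure(list(kind = kind, valley_fraction = valley_fraction),
            class = "resolution_criterion")
}

.nq_criterion_met <- function(doublet, R, criterion, mode) {
  prof <- profile_spectrum(doublet, peak_shape(R, mode))
  idx <- .nq_local_maxima(prof$intensity)
  if (length(idx) < 2) return(FALSE)
  if (criterion$kind == "two_maxima") return(TRUE)
  top <- idx[order(-prof$intensity[idx])][1:2]
  a <- min(top); b <- max(top)
  valley <- min(prof$intensity[a:b])
  valley <= criterion$valley_fraction * min(prof$intensity[c(a, b)])
}

#' Minimum FWHM resolution separating a doublet
#'
#' Smallest resolution at which the Gaussian profile of two sticks
#' satisfies the separation criterion: either the smallest member of an
#' explicit resolution grid, or (default) bisection to 3 significant
#' figures over R in [1e3, 1e7].
#'
#' @param doublet Two-row (m/z, intensity) sticks.
#' @param criterion A \code{resolution_criterion} (default two maxima).
#' @param mode Peak-shape reference mode, see [peak_shape()].
#' @param grid Optional vector of candidate resolutions; if supplied, the
#'   smallest satisfying member is returned.
#' @return Resolution (dimensionless).
#' @examples
#' d <- data.frame(mz = c(182.0578, 182.0641), intensity = c(1, 0.087))
#' min_resolution(d, grid = c(15000, 30000, 50000, 120000, 240000))  # 50000
#' @export
min_resolution <- function(doublet, criterion = resolution_criterion(),
                           mode = c("at_peak", "orbitrap_sqrt"),
                           grid = NULL) {
  mode <- match.arg(mode)
  doublet <- .nq_as_sticks(doublet)
  if (nrow(doublet) != 2 || doublet$mz[1] == doublet$mz[2])
    stop("doublet must be two sticks at distinct m/z")
  if (!is.null(grid)) {
    for (R in sort(grid)) {
      if (.nq_criterion_met(doublet, R, criterion, mode)) return(R)
    }
    stop("criterion not met at any grid resolution")
  }
  lo <- 1e3; hi <- 1e7
  if (.nq_criterion_met(doublet, lo, criterion, mode)) return(lo)
  if (!.nq_criterion_met(doublet, hi, criterion, mode))
    stop("doublet not separable under this criterion at R <= 1e7")
  while (hi / lo > 1.001) {
    mid <- sqrt(lo * hi)
    if (.nq_criterion_met(doublet, mid, criterion, mode)) hi <- mid
    else lo <- mid
  }
  signif(hi, 3)
}

#' Isotopic interference at the nitrotyrosine reporter pair
#'
#' Quantifies the residual interference between the light and heavy
#' reporter channels from natural isotope abundance: \code{f15N}, the
#' one-15N isotopologue of the light reporter (which lands exactly on the
#' heavy reporter's monoisotopic m/z) as a fraction of the light
#' monoisotopic height; \code{f13C}, the light reporter's one-13C
#' satellite fraction (0.0063 Da above the heavy reporter); and
#' \code{delta13C15N}, the 13C-15N fine-structure spacing in Da.
#'
#' Both fractions are read off the computed fine structure of the light
#' reporter cation C8H9N2O3+ (peak-height ratios relative to the
#' monoisotopic species).
#'
#' @return Named list with \code{f15N}, \code{f13C}, \code{delta13C15N}.
#' @export
reporter_interference_fractions <- function() {
  comp <- comp_add(immonium_ion("Y", "nitro_light")$composition,
                   composition(H = 1))  # cation: neutral + proton's H
  fs <- fine_structure(comp, prune_below = 1e-8)
  mono <- fs$mass[which.max(fs$abundance)]
  pick <- function(delta) {
    i <- which(abs(fs$mass - (mono + delta)) < 2e-4)
    if (length(i) != 1) stop("fine-structure species not found at +",
                             format(delta), " Da")
    fs$abundance[i] / fs$abundance[fs$mass == mono]
  }
  list(f15N = pick(DELTA_N15), f13C = pick(DELTA_C13),
       delta13C15N = DELTA_C13 - DELTA_N15)
}
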