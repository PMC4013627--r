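#' Isotope catalog for mass and fine-structure arithmetic
#'
#' Returns the table of isotopes the package uses for all mass and
#' isotope-pattern computation. Masses and natural abundances are pinned
#' in-code from the standard NIST/IUPAC atomic-weight compilation so that
#' results are reproducible offline. Besides the natural elements, the
#' catalog carries fixed-isotope pseudo-elements used by stable-isotope
#' labels: \code{"N15"} is nitrogen-15 at abundance 1, as installed by
#' nitration with O15NOO- (heavy peroxynitrite).
#'
#' Each entry is a data frame with columns \code{isotope} (nominal mass
#' number), \code{mass} (exact mass, Da, strictly increasing) and
#' \code{abundance} (fraction, summing to 1 per element).
#'
#' @return Named list of data frames, one per element token.
#' @examples
#' cat <- element_catalog()
#' cat$N$mass[2] - cat$N$mass[1]  # the 15N-14N spacing, 0.9970349 Da
#' @export
element_catalog <- function() .nq_catalog

.nq_make_catalog <- function() {
  iso <- function(isotope, mass, abundance)
    data.frame(isotope = isotope, mass = mass, abundance = abundance)
  cat <- list(
    H = iso(c(1L, 2L), c(1.00782503207, 2.01410177785), c(0.999885, 0.000115)),
    C = iso(c(12L, 13L), c(12.0, 13.00335483507), c(0.9893, 0.0107)),
    N = iso(c(14L, 15L), c(14.0030740048, 15.0001088989), c(0.99636, 0.00364)),
    O = iso(c(16L, 17L, 18L),
            c(15.9949146196, 16.9991317012, 17.9991610343),
            c(0.99757, 0.00038, 0.00205)),
    S = iso(c(32L, 33L, 34L, 36L),
            c(31.9720710015, 32.9714589098, 33.96786690, 35.96708076),
            c(0.9499, 0.0075, 0.0425, 0.0001)),
    P = iso(31L, 30.97376163, 1.0),
    Se = iso(c(74L, 76L, 77L, 78L, 80L, 82L),
             c(73.92247593, 75.91921360, 76.91991426, 77.91730909,
               79.91652376, 81.91669940),
             c(0.0089, 0.0937, 0.0763, 0.2377, 0.4961, 0.0873)),
    # fixed-isotope pseudo-elements (abundance 1) for stable-isotope labels
    N15 = iso(15L, 15.0001088989, 1.0),
    C13 = iso(13L, 13.00335483507, 1.0),
    H2  = iso(2L, 2.01410177785, 1.0)
  )
  for (el in names(cat)) {
    stopifnot(abs(sum(cat[[el]]$abundance) - 1) < 1e-6,
              all(diff(cat[[el]]$mass) > 0),
              all(cat[[el]]$mass > 0))
  }
  cat
}

.nq_catalog <- .nq_make_catalog()

#' Physical constants used throughout
#'
#' \code{PROTON_MASS} is the proton mass convention used for all m/z
#' arithmetic (the electron mass is not tracked separately; printed
#' reporter and precursor m/z values match this convention to four
#' decimals). \code{DELTA_N15} is the 15N-14N exact-mass difference, the
#' spacing between the heavy and light nitro groups; \code{DELTA_C13} the
#' 13C-12C difference.
#'
#' @name constants
#' @export
PROTON_MASS <- 1.0072765

#' @rdname constants
#' @export
DELTA_N15 <- .nq_catalog$N$mass[2] - .nq_catalog$N$mass[1]

#' @rdname constants
#' @export
DELTA_C13 <- .nq_catalog$C$mass[2] - .nq_catalog$C$mass[1]
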