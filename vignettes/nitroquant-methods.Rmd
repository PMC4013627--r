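---
title: "Methods: stable-isotope-coded nitrotyrosine quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable-isotope-coded nitrotyrosine quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroquant)
```

## The measurement model

Nitration converts tyrosine to 3-nitrotyrosine (+NO₂ − H, +44.9851 Da).
An internal standard nitrated with ¹⁵N-peroxynitrite carries the same
modification shifted by exactly the ¹⁵N–¹⁴N mass difference,
0.9970349 Da. When a light/heavy nitropeptide pair is co-isolated for
MS/MS, the nitrotyrosine immonium/a₁ reporter ions appear at m/z
181.0608 (light) and 182.0578 (heavy), and the per-scan intensity ratio
of the pair estimates the relative amount of light (sample) versus
heavy (spike-in) nitration. Two ions are treated as one reporter
species: for an N-terminal nitrotyrosine the a₁ ion has the same
composition as the internal immonium ion, so no distinction is made.

Three isotopic facts shape the design, and all three are *computed*
here from the pinned isotope catalog rather than hard-coded:

1. The light reporter's one-¹⁵N isotopologue falls exactly on the heavy
   reporter m/z. Its height is `f15N = 2 × a(¹⁵N)/a(¹⁴N) ≈ 0.73%` of the
   light monoisotopic peak (`reporter_interference_fractions()`), below
   1% and thus negligible for rough work but removed by the default
   `"n15"` correction:
   `I_heavy,corr = I_heavy − f15N · I_light`.
2. The light reporter's one-¹³C satellite sits only
   Δ(¹³C) − Δ(¹⁵N) = 0.00632 Da *above* the heavy reporter. Resolving it
   requires FWHM resolution ≥ 50,000 at m/z 182; the optional `"c13"`
   correction models residual Gaussian leakage at lower resolutions
   (at the default MS2 setting of 120,000 the term is below 0.1% and
   the correction is off by default).
3. At the precursor level (e.g. the +3 nitrated angiotensin I pair at
   m/z 447.89/448.23) the heavy monoisotopic peak and the light ¹³C
   isotope peak are separated by 0.00632/z Da. For z = 3 a 10%-valley
   separation needs resolution beyond 400,000 FWHM — beyond routine
   acquisition, which is why quantitation happens in MS/MS, not in
   survey scans.

## Mass conventions

m/z = (M + z·1.0072765)/z with a fixed proton-mass constant; the
electron mass is not tracked separately (printed reporter and precursor
values match this convention to four decimals). Fragment conventions:
b = prefix residues + proton, y = suffix + H₂O + proton, a = b − CO.
Modifications are composition add/remove pairs, never bare deltas, so
isotope patterns of modified species stay exact. Isotope masses and
abundances are pinned in-code from the standard NIST/IUPAC compilation;
`element_catalog()` exposes them.

## Isotope fine structure and resolution modeling

`fine_structure()` expands each element's isotopologue distribution
exactly (multinomial over isotope count vectors) and convolves across
elements, keeping distinct exact masses separate. Species whose masses
agree to 10⁻⁹ Da are merged; species below `prune_below` (default 10⁻⁶)
of the base peak are dropped and the rest renormalized. Intermediate
pruning runs three orders of magnitude below the final threshold, so
reported abundances are unaffected; with `prune_below = 0` the
expansion is exhaustive and conserves total abundance to 10⁻⁹
(practical up to a few dozen atoms — the test suite cross-checks
against an independent atom-by-atom convolution oracle there).

Peaks are modeled as Gaussians with FWHM = m/R (`peak_shape()`,
`"at_peak"`). An `"orbitrap_sqrt"` mode (FWHM = m/(R·√(400/m))) is
provided because instrument settings are quoted at m/z 400; the
published resolution claims read naturally as at-peak values, so that
is the default. Lorentzian/Voigt shapes are not modeled — the
method's argument is made entirely in FWHM terms, and at the
resolutions involved the shape choice does not move the grid answer.

"Separated" is not a single criterion, so `min_resolution()` exposes
two: *two distinct local maxima*, and *valley below a fraction of the
smaller apex* (default 0.10). Profiles are sampled at FWHM/50 over the
sticks ± 5 FWHM; the minimal resolution is found by bisection on
[10³, 10⁷] to three significant figures, or as the smallest member of
an explicit instrument-style grid. For the precursor doublet the
default stick intensities are (1.0 heavy monoisotopic, 0.67 light ¹³C
satellite), the 0.67 being the A+1 fraction implied by nitrated
angiotensin I's 62 carbons at a 1:1 mix; both are overridable.

## What the simulator emulates — and what it does not

`generate_run()` emulates the acquisition used for the spike-in
experiments: survey scans over m/z 400–2000, MS/MS on the top 3 most
abundant precursor peaks per cycle, isolation width 5 m/z, dynamic
exclusion 30 s after one repeat, 240,000/120,000 nominal resolutions.
Elution is Gaussian (default σ = 0.08 min); MS1 scans carry each
species' first three isotope peaks; MS2 scans sum b/y fragments and
reporter ions of *every* species whose monoisotopic precursor lies in
the isolation window, so a light/heavy pair (spacing 0.9970349/z ≤ 0.5)
always co-fragments. Reporter intensities are proportional to species
abundance, with a flat fragment base intensity and an immonium-yield
factor of 3 (fragment intensity modeling is deliberately crude: no
collision-energy dependence). Crucially, the light reporter's ¹⁵N and
¹³C satellites are planted at their computed heights, so the heavy
channel carries the same isotopic interference real data would, and
the `"n15"` correction is exercised honestly.

Noise (all seeded): 2 ppm Gaussian m/z jitter, 5% log-normal intensity
noise, 30 exponential background peaks per MS2 scan drawn away from a
±0.02 m/z reporter guard band (an adversarial mode instead plants
decoys 0.01–0.05 m/z from the reporters to stress the ppm tolerance).
The defaults are ordinary modern-Orbitrap figures: sub-3-ppm mass
error and single-digit-percent intensity repeatability.

What passing tests on these runs shows: the detection logic, window
arithmetic, interference correction, grouping and normalization recover
known ratios under realistic mass error and intensity noise. What they
do not show: robustness to chromatographic tailing, charge-envelope
overlap, co-eluting isobaric interference (observed in the real data
for one peptide), detector saturation, or electron-transfer artifacts —
none of which the generator produces.

`table1_fixture()` reproduces the dilution design itself: a 1:1
reference, three 0.25:1 technical replicates (consecutive seeds), and
one 0.10:1 run, each containing nitro-YLYEIAR and
nitro-YIC(cam)DNQDTISSK as light/heavy pairs (heavy apex abundance
1000 units) plus three unmodified background peptides. Replicates share
the acquisition schedule (pre-noise truth is deterministic given the
species list) and differ in the noise draws, mirroring technical
replication of one sample.

## Detection, grouping, normalization

`find_reporter_pair()` matches, per channel, the most intense peak
within ±10 ppm (ties by smaller |ppm|). Ten ppm is wide against
calibrated mass error yet 3.5× narrower than the 35 ppm that would
admit the light ¹³C satellite into the heavy channel — the test suite
pins that rejection. The diagnostic chromatogram default half-width is
±0.001 Da, the narrow-window setting that isolates true reporter scans
from the crowded nominal-mass trace. Heavy-only scans (no light
partner) are retained as identifications with undefined ratio: the
heavy reporter alone marks candidate endogenous nitration sites.

Peak *heights* are ratioed, not areas: the reporters are single
centroids, and scan-to-scan aggregation supplies the averaging.
Grouping clusters hits by precursor m/z modulo the heavy/light offset
(0.9970349/z) and the isotope spacing (1.0033548/z, for scans triggered
on A+1/A+2 peaks), within 10 ppm and 0.5 min RT contiguity; the group
representative is the lightest selected precursor, which stays on the
isotope grid and therefore matches across runs. Per group the valid
scan ratios give an unweighted mean and sample SD (n ≥ 2); an
intensity-weighted mean is available by config. A scan whose corrected
heavy intensity is non-positive is flagged invalid and excluded.

Normalization divides the condition group mean by the matched
reference (1:1) group mean, with first-order error propagation
assuming independence. Two orders are implemented — aggregate then
normalize (default), and normalize each scan then average — because
the published worked values are ambiguous about the order for one
replicate; the means coincide, only the SD bookkeeping differs, and
neither order is claimed as the original procedure.

## Numerical and degenerate-input choices

* Empty composition → mass 0; empty spectrum → no hit; run without MS2
  scans → empty (not failing) chromatogram and hit table.
* Composition subtraction that would go negative, unknown element
  tokens, non-positive tolerances, charges < 1, and modifications on
  non-target residues are all hard errors raised before any I/O.
* Ties in reporter matching: intensity first, then |ppm|.
* `min_resolution()` bisects on a log scale and reports the upper
  bracket to 3 significant figures; an unseparable doublet (criterion
  unmet at R = 10⁷) is an explicit error, not a large number.
* mzML I/O is delegated to mzR/proteowizard; retention times are
  minutes in memory, seconds on disk. Profile spectra are centroided on
  load by local-maximum picking with 3-point parabolic refinement. The
  writer does not serialize free-text run metadata (an in-memory
  annotation only); everything the pipeline consumes — peaks, levels,
  RTs, precursor and isolation fields — round-trips.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at desk scale: 5-minute runs, 2-second cycles (~150 survey scans,
~50 MS/MS scans, 5–6 reporter-pair scans per nitropeptide per run), and
fine-structure expansions up to the ~180-atom nitrated angiotensin I
composition. The full suite completes in well under a minute; the
acceptance computation in a few seconds.

## Known limitations

* No peptide-spectrum matching, database search, or FDR control — the
  pipeline identifies and quantifies reporter-bearing scans; sequence
  assignment is delegated to a search engine.
* No MS1 (survey-scan) doublet quantitation: at the precursor level the
  required resolution (>400,000 FWHM for a +3 pair, computed by
  `min_resolution()`) exceeds routine instruments; the package computes
  the requirement but does not attempt the quantitation.
* The simulator's fragment intensity model is flat; absolute
  intensities and HCD energy dependence are out of scope.
* Natural ¹⁵N interference is corrected at the reporter level only;
  sequence-specific ¹⁵N effects on precursor isotope envelopes are not
  modeled.
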