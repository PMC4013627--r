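# Reporter detection, diagnostic chromatograms, ratios, grouping,
# normalization.

spec2 <- function(mz, intensity, id = "s1", rt = 1) {
  o <- order(mz)
  ms_spectrum(id, 2L, rt, mz[o], intensity[o],
              precursor = list(mz = 486.74, charge = 2L, iso_center = 486.74,
                               iso_width = 5))
}

test_that("both reporter channels are matched with signed ppm errors", {
  h <- find_reporter_pair(spec2(c(181.0607, 182.0579), c(500, 1000)),
                          tol_ppm = 10)
  expect_equal(h$light_intensity, 500)
  expect_equal(h$heavy_intensity, 1000)
  expect_lt(h$light_ppm, 0)   # matched slightly below the exact mass
  expect_gt(h$heavy_ppm, 0)   # and slightly above
  expect_lt(max(abs(c(h$light_ppm, h$heavy_ppm))), 1)
  expect_error(find_reporter_pair(spec2(181.0608, 1), tol_ppm = 0),
               "positive")
})

test_that("the narrow window rejects the light 13C satellite", {
  # 182.0641 is ~35 ppm from the heavy reporter: must NOT match at 10 ppm
  h <- find_reporter_pair(spec2(c(181.0608, 182.0641), c(500, 43)),
                          tol_ppm = 10)
  expect_equal(h$light_intensity, 500)
  expect_true(is.na(h$heavy_intensity))
  # and an empty spectrum yields no hit at all
  expect_null(find_reporter_pair(
    ms_spectrum("e", 2L, 1, numeric(0), numeric(0)), 10))
})

test_that("channel matching picks the most intense in-window peak", {
  h <- find_reporter_pair(spec2(c(181.0604, 181.0610), c(900, 100)), 10)
  expect_equal(h$light_intensity, 900)
  # tie on intensity: smaller |ppm| wins
  h2 <- find_reporter_pair(spec2(c(181.0601, 181.0609), c(100, 100)), 10)
  expect_equal(h2$light_mz, 181.0609)
})

test_that("detection specificity is exact on noise-free runs", {
  out <- cached_fixture("nf_pair", noise_free_pair_run())
  hits <- detect_reporters(out$run, tol_ppm = 5.5)
  heavy_scans <- hits$scan_id[!is.na(hits$heavy_intensity)]
  manifest_heavy <- out$manifest$scan_id[out$manifest$true_heavy > 0]
  expect_setequal(heavy_scans, manifest_heavy)
})

test_that("diagnostic chromatogram marks exactly the heavy-bearing scans", {
  out <- cached_fixture("nf_pair", noise_free_pair_run())
  ric <- diagnostic_chromatogram(out$run, half_width = 0.001)
  expect_equal(nrow(ric), nrow(out$manifest))
  nz <- ric$scan_id[ric$intensity > 0]
  expect_setequal(nz, out$manifest$scan_id[out$manifest$true_heavy > 0 |
                                             out$manifest$true_light > 0])
  expect_error(diagnostic_chromatogram(out$run, half_width = 0), "positive")
  # no MS2 scans -> empty chromatogram
  empty <- ms_run(list(ms_spectrum("a", 1L, 0.1, 400, 10)))
  expect_equal(nrow(diagnostic_chromatogram(empty)), 0)
})

test_that("widening the diagnostic window never loses scans", {
  fx <- cached_fixture("adv",
    generate_run(list(
      sim_species("YLYEIAR 1:nitro_light", 2, 400, 1.0, id = "l"),
      sim_species("YLYEIAR 1:nitro_heavy", 2, 1000, 1.0, id = "h")),
      acq = acq_config(run_length = 2.2),
      noise = noise_model(adversarial = TRUE), seed = 9))
  narrow <- diagnostic_chromatogram(fx$run, half_width = 0.001)
  for (hw in c(0.01, 0.1, 1.0)) {
    wide <- diagnostic_chromatogram(fx$run, half_width = hw)
    expect_true(all(wide$intensity[narrow$intensity > 0] > 0))
    expect_gte(sum(wide$intensity > 0), sum(narrow$intensity > 0))
  }
})

test_that("per-scan ratios apply the 15N correction arithmetic", {
  expect_equal(per_scan_ratio(250, 1000, corrections = character(0)), 0.25)
  intf <- reporter_interference_fractions()
  expect_equal(per_scan_ratio(1000, 1000), 1000 / (1000 - intf$f15N * 1000))
  expect_equal(per_scan_ratio(1000, 1000), 1.0074, tolerance = 1e-3)
  # correction always increases the ratio, by 1/(1 - f15N * raw)
  for (raw in c(0.1, 0.25, 1, 2)) {
    r0 <- per_scan_ratio(raw, 1, corrections = character(0))
    r1 <- per_scan_ratio(raw, 1)
    expect_gt(r1, r0)
    expect_equal(r1, r0 / (1 - intf$f15N * raw), tolerance = 1e-12)
  }
  # corrected heavy intensity <= 0 flags the scan invalid
  expect_true(is.na(per_scan_ratio(1000, 5)))
  expect_true(is.na(per_scan_ratio(NA, 1000)))
})

test_that("the 13C leakage term is negligible at the MS2 setting", {
  r_n15 <- per_scan_ratio(1000, 1000, corrections = "n15")
  r_both <- per_scan_ratio(1000, 1000, corrections = c("n15", "c13"),
                           resolution = 120000)
  expect_lt(abs(r_both - r_n15) / r_n15, 0.002)
  # at very low resolution the leakage becomes material
  r_low <- per_scan_ratio(1000, 1000, corrections = c("n15", "c13"),
                          resolution = 5000)
  expect_gt(abs(r_low - r_n15) / r_n15, 0.002)
})

test_that("ratios are invariant under intensity rescaling", {
  l <- c(250, 300, 260); h <- c(1000, 1100, 980)
  for (k in c(1e-3, 7, 1e4)) {
    expect_equal(per_scan_ratio(k * l, k * h), per_scan_ratio(l, h),
                 tolerance = 1e-12)
  }
  out <- cached_fixture("nf_pair", noise_free_pair_run())
  scaled <- out$run
  scaled$spectra <- lapply(scaled$spectra, function(s) {
    s$intensity <- s$intensity * 137
    s
  })
  g1 <- group_and_aggregate(detect_reporters(out$run))
  g2 <- group_and_aggregate(detect_reporters(scaled))
  expect_equal(g1$mean, g2$mean, tolerance = 1e-12)
})

test_that("grouping clusters by aligned precursor and aggregates scans", {
  mk <- function(id, rt, pmz, l, h) data.frame(
    scan_id = id, rt = rt, precursor_mz = pmz, charge = 2L,
    light_mz = 181.0608, light_intensity = l, light_ppm = 0,
    heavy_mz = 182.0578, heavy_intensity = h, heavy_ppm = 0)
  hits <- rbind(
    mk("s1", 1.00, 486.740, 240, 1000),
    mk("s2", 1.02, 486.740 + DELTA_N15 / 2, 250, 1000),  # heavy-mono pick
    mk("s3", 1.04, 486.740, 260, 1000),
    mk("s4", 3.00, 744.820, 500, 1000))                  # different peptide
  g <- group_and_aggregate(hits, corrections = character(0))
  expect_equal(nrow(g), 2)
  g1 <- g[g$precursor_mz < 500, ]
  expect_equal(g1$n, 3)
  expect_equal(g1$mean, 0.25, tolerance = 1e-9)
  expect_equal(g1$sd, 0.01, tolerance = 1e-9)
  # single-scan group: SD absent
  expect_true(is.na(g$sd[g$precursor_mz > 500]))
  expect_equal(g$mean[g$precursor_mz > 500], 0.5)
})

test_that("the spike-in fixture yields one group per nitropeptide", {
  fx <- cached_fixture("fx12", table1_fixture(seed = 12))
  g <- group_and_aggregate(detect_reporters(fx$r025a$run))
  expect_equal(nrow(g), 2)
  expect_equal(sort(g$precursor_mz),
               c(mz(peptide_mass("YLYEIAR 1:nitro_light"), 2),
                 mz(peptide_mass("YICDNQDTISSK 1:nitro_light 3:cam"), 2)),
               tolerance = 1e-4)
})

test_that("internal-standard normalization reproduces worked values", {
  # dividing raw condition means by the raw reference mean; the inputs
  # are 2-decimal roundings, so agreement holds to one unit in the last
  # printed digit
  n1 <- normalize_ratio(list(mean = 0.16, sd = 0.01),
                        list(mean = 0.69, sd = 0.02))
  expect_equal(round(n1$normalized, 2), 0.23)
  n2 <- normalize_ratio(list(mean = 0.17, sd = 0.01),
                        list(mean = 0.69, sd = 0.02))
  expect_lt(abs(n2$normalized - 0.24), 0.01)
  # the reference normalized to itself is exactly 1
  ref <- list(mean = 0.69, sd = 0.02)
  expect_identical(normalize_ratio(ref, ref)$normalized, 1)
  # first-order error propagation from both SDs
  expect_equal(n1$sd,
               (0.16 / 0.69) * sqrt((0.01 / 0.16)^2 + (0.02 / 0.69)^2),
               tolerance = 1e-12)
  expect_error(normalize_ratio(list(mean = 0.2, sd = 0.01),
                               list(mean = 0, sd = 0.01)), "positive")
})

test_that("heavy-only hits are kept as identifications without ratios", {
  hits <- data.frame(
    scan_id = c("s1", "s2"), rt = c(1, 1.02), precursor_mz = c(487.2, 487.2),
    charge = 2L, light_mz = c(NA, 181.0608),
    light_intensity = c(NA, 200), light_ppm = c(NA, 0),
    heavy_mz = 182.0578, heavy_intensity = c(900, 800), heavy_ppm = 0)
  g <- group_and_aggregate(hits)
  expect_equal(g$n, 1)            # only the complete pair quantifies
  expect_equal(g$n_heavy_only, 1) # the heavy-only scan is still counted
})

test_that("mixing-ratio recovery stays within three propagated SDs", {
  out <- generate_run(
    list(sim_species("YLYEIAR 1:nitro_light", 2, 250, 1.6, id = "l"),
         sim_species("YLYEIAR 1:nitro_heavy", 2, 1000, 1.6, id = "h")),
    acq = acq_config(run_length = 3.2), seed = 7)
  g <- group_and_aggregate(detect_reporters(out$run))
  expect_equal(nrow(g), 1)
  expect_lt(abs(g$mean - 0.25), 3 * g$sd)
  # noise off: recovery within 10% of nominal across the design range
  for (nominal in c(1, 0.5, 0.25, 0.1)) {
    nf <- noise_free_pair_run(ratio = nominal, seed = 3)
    gn <- group_and_aggregate(detect_reporters(nf$run))
    expect_lt(abs(gn$mean - nominal) / nominal, 0.10)
  }
})
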