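# Isotope fine structure, Gaussian profiles, and minimum-resolution
# determination.

test_that("fine structure of single elements matches catalog values", {
  fs <- fine_structure("C1")
  expect_equal(fs$mass, c(12.0, 13.0033548), tolerance = 1e-6)
  expect_equal(fs$abundance, c(0.9893, 0.0107))
  expect_error(fine_structure(composition(C = 1), prune_below = 1), "prune")
})

test_that("light reporter fine structure quantifies channel interference", {
  fs <- fine_structure("C8H9N2O3", prune_below = 1e-8)
  mono_i <- which.max(fs$abundance)
  f15 <- fs$abundance[abs(fs$mass - fs$mass[mono_i] - DELTA_N15) < 1e-4] /
    fs$abundance[mono_i]
  expect_length(f15, 1)
  expect_equal(f15, 2 * 0.00364 / 0.99636, tolerance = 1e-6)  # 0.73%
  expect_lt(f15, 0.01)
  # summed A+1 cluster ~9.7% of monoisotopic, dominated by 13C (~8.7%)
  a1 <- abs(fs$mass - fs$mass[mono_i] - 1) < 0.05
  expect_equal(sum(fs$abundance[a1]) / fs$abundance[mono_i], 0.097,
               tolerance = 0.02)
  f13 <- fs$abundance[abs(fs$mass - fs$mass[mono_i] - DELTA_C13) < 1e-4] /
    fs$abundance[mono_i]
  expect_equal(f13, 8 * 0.0107 / 0.9893, tolerance = 1e-6)   # ~8.7%
})

test_that("reporter_interference_fractions agree with fine-structure oracle", {
  intf <- reporter_interference_fractions()
  oracle <- brute_fine_structure("C8H9N2O3")
  mono <- which.max(oracle$abundance)
  o15 <- oracle$abundance[abs(oracle$mass - oracle$mass[mono] - DELTA_N15) <
                            1e-6] / oracle$abundance[mono]
  o13 <- oracle$abundance[abs(oracle$mass - oracle$mass[mono] - DELTA_C13) <
                            1e-6] / oracle$abundance[mono]
  expect_equal(intf$f15N, o15, tolerance = 1e-9)
  expect_equal(intf$f13C, o13, tolerance = 1e-9)
  expect_equal(intf$delta13C15N, 0.00632, tolerance = 1e-5)
  expect_lt(intf$f15N, 0.01)
})

test_that("fine structure conserves abundance and matches the brute-force
          oracle for small compositions", {
  cases <- list("C5H7NO3", "C3H5NOS", composition(C = 8, H = 9, N = 2, O = 3),
                composition(N15 = 1, C = 7, H = 9, N = 1, O = 3),
                "C6H11NO")  # all at most 30 atoms
  # bin both patterns at 1e-7 Da before comparing: species that happen to
  # coincide to ~1e-9 Da may fall on either side of a rounding boundary
  bin <- function(df) {
    key <- round(df$mass, 7)
    data.frame(mass = sort(unique(key)),
               abundance = rowsum(df$abundance, key, reorder = TRUE)[, 1])
  }
  for (comp in cases) {
    fs <- fine_structure(comp, prune_below = 0)
    expect_equal(sum(fs$abundance), 1, tolerance = 1e-9)
    a <- bin(fs); b <- bin(brute_fine_structure(comp))
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$mass, b$mass, tolerance = 1e-9)
    expect_lt(max(abs(a$abundance - b$abundance)), 1e-12)
  }
  # pruning keeps the pattern normalized
  fs <- fine_structure("C62H89N17O14", prune_below = 1e-6)
  expect_equal(sum(fs$abundance), 1, tolerance = 1e-9)
  expect_true(all(diff(fs$mass) > 0))
})

test_that("fixed-isotope tokens shift the pattern without broadening it", {
  light <- fine_structure(composition(C = 8, H = 9, N = 2, O = 3),
                          prune_below = 0)
  heavy <- fine_structure(composition(C = 8, H = 9, N = 1, N15 = 1, O = 3),
                          prune_below = 0)
  # the heavy monoisotopic sits exactly one 15N-14N spacing up
  expect_equal(heavy$mass[which.max(heavy$abundance)] -
                 light$mass[which.max(light$abundance)],
               DELTA_N15, tolerance = 1e-9)
})

test_that("profile synthesis obeys Gaussian algebra", {
  # single stick: apex at the stick m/z with the stick height
  p <- profile_spectrum(data.frame(mz = 500, intensity = 2), 60000)
  expect_equal(p$mz[which.max(p$intensity)], 500, tolerance = 1e-5)
  expect_equal(max(p$intensity), 2, tolerance = 1e-6)
  # two equal sticks exactly 1 FWHM apart: midpoint equals stick height
  # (each Gaussian contributes exactly half)
  fw <- 200 / 50000
  p2 <- profile_spectrum(data.frame(mz = c(200, 200 + fw),
                                    intensity = c(1, 1)),
                         peak_shape(50000), grid_step = fw / 200)
  mid <- which.min(abs(p2$mz - (200 + fw / 2)))
  expect_equal(p2$intensity[mid], 1, tolerance = 1e-3)
  expect_error(profile_spectrum(data.frame(mz = numeric(0),
                                           intensity = numeric(0)), 1e5),
               "empty")
  expect_error(profile_spectrum(data.frame(mz = 500, intensity = 1), 1e5,
                                grid_step = 1), "grid_step")
})

test_that("orbitrap-style resolution mode widens peaks above m/z 400", {
  sh <- peak_shape(240000, "orbitrap_sqrt")
  expect_equal(fwhm_at(sh, 400), 400 / 240000, tolerance = 1e-12)
  expect_gt(fwhm_at(sh, 800), 800 / 240000)
  expect_equal(fwhm_at(peak_shape(240000), 800), 800 / 240000)
})

test_that("reporter-region doublet resolves on the documented grid", {
  d <- data.frame(mz = c(182.0578, 182.0641), intensity = c(1, 0.0865))
  grid <- c(15000, 30000, 50000, 120000, 240000)
  expect_equal(min_resolution(d, grid = grid), 50000)
  # oracle: direct profile evaluation at each grid point
  n_max <- vapply(grid, function(R)
    oracle_profile_max_count(d$mz, d$intensity, R), numeric(1))
  expect_equal(grid[min(which(n_max >= 2))], 50000)
  # at the top instrument setting the valley is below 1% of the smaller apex
  prof <- profile_spectrum(d, peak_shape(240000))
  imax <- which(diff(sign(diff(prof$intensity))) < 0) + 1L
  imax <- imax[prof$intensity[imax] > 1e-6 * max(prof$intensity)]
  expect_length(imax, 2)
  valley <- min(prof$intensity[imax[1]:imax[2]])
  expect_lt(valley, 0.01 * min(prof$intensity[imax]))
})

test_that("precursor doublet needs beyond-instrument resolution", {
  d <- data.frame(mz = c(448.2271, 448.2292), intensity = c(1, 0.67))
  r <- min_resolution(d, resolution_criterion("valley", 0.10))
  expect_gte(r, 400000)
  expect_lt(r, 1e6)
  expect_error(
    min_resolution(data.frame(mz = c(500, 500 + 1e-6),
                              intensity = c(1, 1)),
                   resolution_criterion("valley", 0.10)),
    "not separable")
})

test_that("equal-doublet two-maxima threshold matches the closed form", {
  # two equal Gaussians merge when separation drops below 2*sigma:
  # R* = m * sqrt(2*log(2)) / delta
  m <- 300; delta <- 0.004
  d <- data.frame(mz = c(m, m + delta), intensity = c(1, 1))
  r <- min_resolution(d)
  closed <- m / (delta * sqrt(2 * log(2)))
  expect_equal(r, closed, tolerance = 5e-3)
})

test_that("minimum resolution is monotone in spacing and valley depth", {
  base <- 182.0578
  spacings <- c(0.012, 0.0063, 0.003)
  rs <- vapply(spacings, function(dm)
    min_resolution(data.frame(mz = c(base, base + dm),
                              intensity = c(1, 0.5))), numeric(1))
  expect_true(all(diff(rs) > 0))  # tighter doublet -> higher R
  fracs <- c(0.5, 0.25, 0.10)
  rv <- vapply(fracs, function(f)
    min_resolution(data.frame(mz = c(base, base + 0.0063),
                              intensity = c(1, 0.5)),
                   resolution_criterion("valley", f)), numeric(1))
  expect_true(all(diff(rv) > 0))  # deeper valley required -> higher R
})
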