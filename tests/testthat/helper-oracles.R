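# Independent oracles and cached fixtures shared across test files.

# Brute-force isotope fine structure: convolve one atom at a time,
# merging species of equal exact mass. Independent of the package's
# per-element multinomial expansion.
brute_fine_structure <- function(comp) {
  comp <- if (is.character(comp)) parse_formula(comp) else as_composition(comp)
  cat <- element_catalog()
  mass <- 0; ab <- 1
  for (tok in names(comp)) {
    tab <- cat[[tok]]
    for (k in seq_len(comp[[tok]])) {
      m2 <- as.numeric(outer(mass, tab$mass, `+`))
      a2 <- as.numeric(outer(ab, tab$abundance))
      key <- round(m2, 9)
      ab <- rowsum(a2, key, reorder = TRUE)[, 1]
      wm <- rowsum(m2 * a2, key, reorder = TRUE)[, 1] / ab
      o <- order(wm)
      mass <- unname(wm[o]); ab <- unname(ab[o])
    }
  }
  data.frame(mass = mass, abundance = ab)
}

# Direct profile evaluator used as the oracle for resolution criteria.
oracle_profile_max_count <- function(mzs, heights, R) {
  fw <- mzs / R
  x <- seq(min(mzs) - 5 * max(fw), max(mzs) + 5 * max(fw), by = min(fw) / 60)
  y <- rep(0, length(x))
  for (i in seq_along(mzs))
    y <- y + heights[i] * exp(-4 * log(2) * (x - mzs[i])^2 / fw[i]^2)
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  length(idx[y[idx] > 1e-9 * max(y)])
}

# Cache expensive simulated fixtures across test files (one R session).
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# A small noise-free run with one light/heavy pair at a given ratio.
noise_free_pair_run <- function(ratio = 1, seed = 3) {
  generate_run(
    list(sim_species("YLYEIAR 1:nitro_light", 2, 1000 * ratio, 1.6,
                     id = "pair_light"),
         sim_species("YLYEIAR 1:nitro_heavy", 2, 1000, 1.6,
                     id = "pair_heavy")),
    acq = acq_config(run_length = 3.2),
    noise = noise_off(), seed = seed)
}
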