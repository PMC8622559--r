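# Shared fixtures and independent oracles, built in code.

# A tiny 3-peak spectrum at exact subformula masses of C15H24O.
bht_like_spectrum <- function() {
  ei_spectrum(
    mz = c(monoisotopic_mass("C4H9", as_radical_cation = TRUE),
           monoisotopic_mass("C14H21O", as_radical_cation = TRUE),
           monoisotopic_mass("C15H24O", as_radical_cation = TRUE)),
    intensity = c(400, 1000, 250)
  )
}

# Independent brute-force subformula oracle: full expand.grid over counts,
# neutral masses summed from the same public constants the tests verify
# separately against an external reference.
brute_subformulas <- function(counts, target_mz, tol_ppm) {
  iso <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
           O = 15.99491461956, F = 18.99840322, P = 30.97376163,
           S = 31.97207100, Cl = 34.96885268)
  grid <- expand.grid(lapply(counts, function(n) 0:n))
  names(grid) <- names(counts)
  mass <- as.matrix(grid) %*% iso[names(counts)] - 5.48579909e-4
  keep <- rowSums(grid) > 0 &
    abs(1e6 * (target_mz - mass) / mass) <= tol_ppm
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(character(0))
  apply(grid, 1L, function(cc) {
    cc <- cc[cc > 0]
    format(elemental_formula(cc))
  })
}

# Construct a bare match_result without running the matcher.
fake_match <- function(total, n_frag, molion, dri = NA_real_,
                       name = "X") {
  structure(
    list(record = list(name = name, cas = NA_character_, formula = NULL),
         si_score = total, hrf_score = total, total_score = total,
         si_only = FALSE, annotations = NULL,
         n_fragments_within_tol = as.integer(n_frag),
         molecular_ion_observed = isTRUE(molion), delta_ri = dri,
         mass_list_hit = FALSE),
    class = "match_result"
  )
}

# Small deterministic simulation shared by several tests.
small_sim <- function(seed = 7L, ...) {
  cfg <- sim_config(seed = seed, n_planted = 6L, n_decoys = 6L, ...)
  lib <- make_library(default_formulas(6L), cfg)
  list(cfg = cfg, lib = lib, sim = simulate_runs(lib, cfg))
}
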