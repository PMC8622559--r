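# Synthetic-data generator for hermetic end-to-end validation.
#
# Emulates deconvoluted GC-EI-HRMS features: reference spectra whose peaks
# sit at exact radical-cation subformula masses (random atom-subset
# deletion, not bond-aware fragmentation chemistry), a monotone RI->RT
# model through alkane anchors (so retention-index calculation inverts it
# exactly), triplicate injections with configurable m/z and intensity
# perturbation, spiked internal standards consistent with a configured
# true response factor, and decoy features whose m/z values are shuffled
# across compounds (realistic peak statistics, wrong exact-mass
# structure). Everything is deterministic under the configured seed.

#' Simulation configuration
#'
#' Defaults mirror the acquisition and design they emulate: EI full-scan
#' m/z 40-500, triplicate injections, internal standards spiked at
#' 200 ng/mL, m/z perturbation within 1 ppm and intensity perturbation
#' within 5%.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_planted number of genuine (planted) compounds.
#' @param n_decoys number of shuffled decoy features per replicate.
#' @param mz_noise_ppm half-width of the uniform m/z perturbation, ppm.
#' @param intensity_noise_frac half-width of the uniform multiplicative
#'   intensity perturbation.
#' @param rt_jitter_min half-width of the uniform retention-time jitter,
#'   minutes.
#' @param n_replicates number of injections.
#' @param mass_range acquired m/z range, Th.
#' @param ladder_carbons carbon numbers of the simulated alkane ladder.
#' @param is_spiked_conc internal-standard spiked concentration, ng/mL.
#' @param true_response_factor true detector response, area per ng/mL.
#' @param geom an [extract_geometry()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_planted = 20L, n_decoys = 20L,
                       mz_noise_ppm = 1, intensity_noise_frac = 0.05,
                       rt_jitter_min = 0.02, n_replicates = 3L,
                       mass_range = c(40, 500),
                       ladder_carbons = seq(8L, 40L, by = 2L),
                       is_spiked_conc = 200,
                       true_response_factor = 5000,
                       geom = extract_geometry()) {
  stopifnot(mz_noise_ppm >= 0, intensity_noise_frac >= 0,
            rt_jitter_min >= 0, n_replicates >= 1L,
            length(mass_range) == 2L, mass_range[1] < mass_range[2],
            is_spiked_conc > 0, true_response_factor > 0)
  structure(list(seed = as.integer(seed), n_planted = as.integer(n_planted),
                 n_decoys = as.integer(n_decoys),
                 mz_noise_ppm = mz_noise_ppm,
                 intensity_noise_frac = intensity_noise_frac,
                 rt_jitter_min = rt_jitter_min,
                 n_replicates = as.integer(n_replicates),
                 mass_range = mass_range,
                 ladder_carbons = as.integer(ladder_carbons),
                 is_spiked_conc = is_spiked_conc,
                 true_response_factor = true_response_factor,
                 geom = geom),
            class = "sim_config")
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Default planted-compound formulas
#'
#' Unique molecular formulas drawn from the packaged recycled-LDPE
#' identification table, a realistic mix of additives, esters and
#' polyethylene oligomers.
#'
#' @param n how many formulas.
#' @return character vector of formula strings.
#' @export
default_formulas <- function(n = 20L) {
  fml <- unique(ldpe_identified()$formula)
  if (n > length(fml)) stop("only ", length(fml), " unique formulas available")
  fml[seq_len(n)]
}

# piecewise-linear RI -> RT through the ladder anchors (the exact inverse
# of compute_ri's interpolation); mildly nonlinear anchor spacing
sim_ladder <- function(cfg) {
  cn <- cfg$ladder_carbons
  rt <- 5 + 1.6 * (cn - cn[1]) + 0.012 * (cn - cn[1])^2
  alkane_ladder(cn, rt)
}

ri_to_rt <- function(ri, ladder) {
  ri_anchor <- 100 * ladder$carbon_number
  vapply(ri, function(x) {
    i <- findInterval(x, ri_anchor)
    i <- min(max(i, 1L), nrow(ladder) - 1L)
    t1 <- ladder$rt[i]; t2 <- ladder$rt[i + 1L]
    r1 <- ri_anchor[i]; r2 <- ri_anchor[i + 1L]
    t1 + (t2 - t1) * (x - r1) / (r2 - r1)
  }, numeric(1))
}

#' Generate a synthetic EI spectral library
#'
#' One record per formula: 8-20 fragment peaks at exact radical-cation
#' subformula masses inside the acquired mass range, log-normal
#' intensities, plus the molecular ion when its m/z fits the range. Each
#' record is assigned a library retention index spread over the ladder.
#' A formula too small for the requested fragment count yields fewer
#' fragments with a warning.
#'
#' @param formulas character vector of molecular formulas.
#' @param cfg a [sim_config()].
#' @return list with `records` (list of [library_record()]) and `truth`
#'   (data.frame: `compound`, `formula`, `library_ri`, `n_peaks`).
#' @export
make_library <- function(formulas, cfg = sim_config()) {
  stopifnot(length(formulas) >= 1L)
  with_seed(cfg$seed, {
    ri_lo <- 100 * (min(cfg$ladder_carbons) + 1)
    ri_hi <- 100 * (max(cfg$ladder_carbons) - 1)
    lib_ri <- sort(stats::runif(length(formulas), ri_lo, ri_hi))
    records <- vector("list", length(formulas))
    for (i in seq_along(formulas)) {
      f <- parse_formula(formulas[i])
      tab <- subformula_table(f)
      in_range <- which(tab$mass >= cfg$mass_range[1] &
                          tab$mass <= cfg$mass_range[2])
      n_frag <- sample(8:20, 1L)
      if (length(in_range) < n_frag) {
        warning("formula ", formulas[i], " supports only ",
                length(in_range), " in-range fragments")
        n_frag <- length(in_range)
      }
      pick <- sample(in_range, n_frag)
      mz <- tab$mass[pick]
      inten <- stats::rlnorm(n_frag, meanlog = log(1000), sdlog = 1)
      mion <- monoisotopic_mass(f, as_radical_cation = TRUE)
      if (mion >= cfg$mass_range[1] && mion <= cfg$mass_range[2] &&
          !any(abs(mz - mion) < 1e-9)) {
        mz <- c(mz, mion)
        inten <- c(inten, stats::rlnorm(1, log(500), 0.5))
      }
      records[[i]] <- library_record(
        name = sprintf("SYN-%03d %s", i, formulas[i]),
        spectrum = ei_spectrum(mz, inten),
        formula = f,
        cas = sprintf("9999-%02d-%d", i %% 100, i %% 10),
        library_ri = lib_ri[i],
        source_tag = "synthetic"
      )
    }
    truth <- data.frame(
      compound = vapply(records, `[[`, character(1), "name"),
      formula = formulas,
      library_ri = lib_ri,
      n_peaks = vapply(records, function(r) nrow(r$spectrum), integer(1)),
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth)
  })
}

#' Build decoy spectra by shuffling m/z across compounds
#'
#' Pools every peak m/z in the library and redistributes them at random,
#' keeping each record's intensity vector and peak count. Decoys carry
#' realistic peak statistics but no exact-mass relationship to any
#' molecular formula.
#'
#' @param records list of [library_record()].
#' @param cfg a [sim_config()] (its seed, offset, drives the shuffle).
#' @return list of decoy `library_record`s named `DECOY-...`, without
#'   formulas or retention indices.
#' @export
make_decoys <- function(records, cfg = sim_config()) {
  with_seed(cfg$seed + 1000L, {
    all_mz <- unlist(lapply(records, function(r) r$spectrum$mz))
    shuffled <- sample(all_mz)
    # tiny deterministic offset so no decoy peak equals a library mass
    shuffled <- shuffled + stats::runif(length(shuffled), 0.02, 0.25)
    k <- 0L
    lapply(seq_along(records), function(i) {
      n <- nrow(records[[i]]$spectrum)
      mz <- shuffled[k + seq_len(n)]
      k <<- k + n
      library_record(
        name = sprintf("DECOY-%03d", i),
        spectrum = ei_spectrum(mz, records[[i]]$spectrum$intensity),
        formula = NULL,
        source_tag = "synthetic-decoy"
      )
    })
  })
}

#' Simulate replicate injections from a synthetic library
#'
#' Planted features take their retention time from the piecewise-linear
#' RI->RT model at the record's library RI (plus uniform jitter) and their
#' spectra from the record perturbed by the configured uniform m/z (ppm)
#' and intensity noise. Peak areas follow the configured true response
#' factor applied to log-normal true concentrations. Decoy features get
#' shuffled spectra and random retention times. Internal-standard areas
#' are consistent with the same response factor.
#'
#' @param library result of [make_library()].
#' @param cfg a [sim_config()].
#' @return list with `features` (all replicates), `ladder`, `standards`
#'   (input for [average_response_factor()]), `truth` (per planted
#'   compound: true concentration ng/mL and true migration mg/kg) and
#'   `decoy_ids` (feature ids of decoys).
#' @export
simulate_runs <- function(library, cfg = sim_config()) {
  records <- library$records[seq_len(min(cfg$n_planted,
                                         length(library$records)))]
  ladder <- sim_ladder(cfg)
  with_seed(cfg$seed + 2000L, {
    true_conc <- stats::rlnorm(length(records), log(120), 0.8)  # ng/mL
    decoys <- if (cfg$n_decoys > 0L) {
      dec_src <- make_decoys(library$records, cfg)
      dec_src[seq_len(min(cfg$n_decoys, length(dec_src)))]
    } else list()
    features <- list()
    for (rep_i in seq_len(cfg$n_replicates)) {
      rid <- sprintf("R%d", rep_i)
      for (i in seq_along(records)) {
        rec <- records[[i]]
        rt <- ri_to_rt(rec$library_ri, ladder) +
          stats::runif(1, -1, 1) * cfg$rt_jitter_min
        spec <- perturb_spectrum(rec$spectrum, cfg)
        area <- true_conc[i] * cfg$true_response_factor *
          (1 + stats::runif(1, -1, 1) * cfg$intensity_noise_frac)
        features[[length(features) + 1L]] <- ms_feature(
          feature_id = sprintf("P%03d", i), rt = rt, area = area,
          spectrum = spec, replicate_id = rid
        )
      }
      for (i in seq_along(decoys)) {
        rt <- stats::runif(1, min(ladder$rt), max(ladder$rt))
        spec <- perturb_spectrum(decoys[[i]]$spectrum, cfg)
        features[[length(features) + 1L]] <- ms_feature(
          feature_id = sprintf("D%03d", i), rt = rt,
          area = stats::rlnorm(1, log(2e5), 1), spectrum = spec,
          replicate_id = rid
        )
      }
    }
    is_formulas <- c("C6H6O", "C13H10O", "C24H38O4")
    standards <- data.frame(
      name = c("IS-phenol", "IS-benzophenone", "IS-phthalate"),
      cas = c("IS-1", "IS-2", "IS-3"),
      spiked_conc_ng_ml = rep(cfg$is_spiked_conc, 3L),
      formula = is_formulas,
      stringsAsFactors = FALSE
    )
    standards$areas <- lapply(seq_len(3L), function(i) {
      cfg$is_spiked_conc * cfg$true_response_factor *
        (1 + stats::runif(cfg$n_replicates, -1, 1) * cfg$intensity_noise_frac)
    })
    truth <- library$truth[seq_along(records), , drop = FALSE]
    truth$true_conc_ng_ml <- true_conc
    truth$true_migration_mg_kg <-
      concentration_to_migration(true_conc / 1e6, cfg$geom)
    list(features = features, ladder = ladder, standards = standards,
         truth = truth,
         decoy_ids = if (length(decoys)) sprintf("D%03d", seq_along(decoys))
                     else character(0))
  })
}

perturb_spectrum <- function(spec, cfg) {
  n <- nrow(spec)
  mz <- spec$mz * (1 + stats::runif(n, -1, 1) * cfg$mz_noise_ppm * 1e-6)
  inten <- spec$intensity *
    (1 + stats::runif(n, -1, 1) * cfg$intensity_noise_frac)
  ei_spectrum(mz, pmax(inten, 1e-12))
}
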