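test_that("library generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 5L, n_planted = 4L)
  f <- default_formulas(4L)
  l1 <- make_library(f, cfg)
  l2 <- make_library(f, cfg)
  p1 <- withr::local_tempfile(fileext = ".msp")
  p2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(l1$records, p1)
  write_msp(l2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(l1$truth, l2$truth)
})

test_that("every generated library peak re-annotates to a subformula at 0 ppm", {
  cfg <- sim_config(seed = 6L, n_planted = 3L)
  lib <- make_library(default_formulas(3L), cfg)
  for (rec in lib$records) {
    hits <- vapply(rec$spectrum$mz, function(mz) {
      nrow(enumerate_subformulas(rec$formula, mz, tol_ppm = 0.001)) > 0L
    }, logical(1))
    expect_true(all(hits))
    expect_equal(hrf_score(rec$spectrum, rec$formula), 100)
  }
})

test_that("decoy spectra lose their exact-mass structure", {
  cfg <- sim_config(seed = 8L, n_planted = 5L)
  lib <- make_library(default_formulas(5L), cfg)
  decoys <- make_decoys(lib$records, cfg)
  for (i in seq_along(decoys)) {
    expect_lt(hrf_score(decoys[[i]]$spectrum, lib$records[[i]]$formula), 50)
  }
})

test_that("simulated runs are deterministic and carry usable ground truth", {
  sm1 <- small_sim()
  sm2 <- small_sim()
  expect_identical(sm1$sim$truth, sm2$sim$truth)
  expect_identical(vapply(sm1$sim$features, `[[`, numeric(1), "rt"),
                   vapply(sm2$sim$features, `[[`, numeric(1), "rt"))
  tr <- sm1$sim$truth
  expect_true(all(c("true_conc_ng_ml", "true_migration_mg_kg") %in% names(tr)))
  expect_equal(tr$true_migration_mg_kg,
               concentration_to_migration(tr$true_conc_ng_ml / 1e6))
})

test_that("internal-standard areas invert to the configured response factor", {
  sm <- small_sim()
  rf <- average_response_factor(sm$sim$standards)
  expect_lt(abs(rf / sm$cfg$true_response_factor - 1),
            sm$cfg$intensity_noise_frac + 1e-9)
  noiseless <- small_sim(intensity_noise_frac = 0)
  expect_equal(average_response_factor(noiseless$sim$standards),
               noiseless$cfg$true_response_factor, tolerance = 1e-12)
})

test_that("with zero noise the pipeline recovers identities and migrations exactly", {
  sm <- small_sim(mz_noise_ppm = 0, intensity_noise_frac = 0,
                  rt_jitter_min = 0)
  res <- run_screen(sm$sim$features, sm$lib$records, sm$sim$ladder,
                    sm$sim$standards, default_cramer_class = "III")
  tab <- res$identifications
  expect_setequal(tab$compound, sm$lib$truth$compound)
  expect_equal(tab$delta_ri, rep(0, nrow(tab)), tolerance = 1e-9)
  m <- merge(res$quantified, sm$sim$truth, by = "compound")
  expect_equal(m$migration_mg_kg, m$true_migration_mg_kg, tolerance = 1e-12)
})

test_that("with no planted compounds only decoys remain and nothing is identified", {
  cfg <- sim_config(seed = 9L, n_planted = 0L, n_decoys = 4L)
  lib <- make_library(default_formulas(4L), cfg)
  sim <- simulate_runs(lib, cfg)
  expect_true(all(grepl("^D", vapply(sim$features, `[[`, character(1),
                                     "feature_id"))))
  tab <- build_identification_table(sim$features, lib$records, sim$ladder)
  expect_identical(nrow(tab), 0L)
})
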