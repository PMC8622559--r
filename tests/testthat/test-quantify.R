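make_standards <- function(ratios, conc = 200) {
  data.frame(name = paste0("IS", seq_along(ratios)),
             spiked_conc_ng_ml = conc,
             areas = I(lapply(ratios, function(r) r * conc)))
}

test_that("average response factor is the mean area/concentration ratio", {
  one <- data.frame(name = "IS1", spiked_conc_ng_ml = 200,
                    areas = I(list(1.0e6)))
  expect_equal(average_response_factor(one), 5000)
  eq <- make_standards(c(4200, 4200, 4200))
  expect_equal(average_response_factor(eq), 4200)
  mix <- make_standards(c(4000, 5000, 6000))
  expect_equal(average_response_factor(mix), 5000)
  expect_error(average_response_factor(one[0, ]), "1")
})

test_that("concentration estimation inverts the response factor linearly", {
  expect_equal(estimate_concentration(5000 * 12.5, 5000), 12.5)
  expect_equal(estimate_concentration(0, 5000), 0)
  expect_equal(estimate_concentration(2 * 777, 1), 2 * 777)
  expect_error(estimate_concentration(100, 0), "positive")
})

test_that("migration conversion follows the geometry chain", {
  expect_equal(concentration_to_migration(0.001), 0.024)
  expect_equal(concentration_to_migration(0), 0)
  half_area <- extract_geometry(film_area = 0.125)
  expect_equal(concentration_to_migration(0.001, half_area),
               2 * concentration_to_migration(0.001))
})

test_that("migration is homogeneous of degree 1 in peak area", {
  rf <- 4321
  areas <- c(10, 1e3, 7.7e6)
  m1 <- concentration_to_migration(estimate_concentration(areas, rf) / 1e6)
  m2 <- concentration_to_migration(estimate_concentration(2 * areas, rf) / 1e6)
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
})

test_that("calibration recovers planted lines exactly and flags extrapolation", {
  curve <- data.frame(conc = c(20, 50, 100, 200, 500))
  curve$area_ratio <- 0.004 * curve$conc + 0.01
  mid <- calibrate_and_quantify(curve, 0.004 * 150 + 0.01)
  expect_equal(mid$conc, 150, tolerance = 1e-9)
  expect_false(mid$extrapolated)
  high <- calibrate_and_quantify(curve, 0.004 * 900 + 0.01)
  expect_equal(high$conc, 900, tolerance = 1e-9)
  expect_true(high$extrapolated)
  expect_error(calibrate_and_quantify(curve[1:2, ], 0.1), "3 points")
  sing <- data.frame(conc = c(50, 50, 50), area_ratio = c(1, 2, 3))
  expect_error(calibrate_and_quantify(sing, 0.1), "singular")
})

test_that("calibration under 2% multiplicative noise recovers within 5%", {
  set.seed(61)
  for (i in 1:5) {
    conc <- c(20, 50, 100, 200, 350, 500)
    truth <- runif(1, 60, 400)
    noisy <- data.frame(conc = conc,
                        area_ratio = 0.003 * conc * (1 + 0.02 * rnorm(6)))
    est <- calibrate_and_quantify(noisy, 0.003 * truth)
    expect_lt(abs(est$conc / truth - 1), 0.05)
  }
})

test_that("system suitability matches a two-pass RSD oracle and flags mass accuracy", {
  theo <- monoisotopic_mass("C13H10O", as_radical_cation = TRUE)
  reps <- data.frame(
    name = "IS-benzophenone",
    area = c(100, 102, 98), rt_min = c(20.00, 20.01, 20.00),
    observed_mz = rep(theo, 3), formula = "C13H10O"
  )
  out <- system_suitability(reps)
  # textbook two-pass oracle
  two_pass <- function(x) {
    m <- sum(x) / length(x)
    100 * sqrt(sum((x - m)^2) / (length(x) - 1)) / m
  }
  expect_equal(out$rsd_area_pct, two_pass(reps$area), tolerance = 1e-12)
  expect_equal(out$rsd_rt_pct, two_pass(reps$rt_min), tolerance = 1e-12)
  expect_equal(out$rsd_area_pct, 2.0)
  expect_equal(out$delta_mass_ppm, 0)
  expect_true(out$mass_ok)

  ident <- reps; ident$area <- 50; ident$rt_min <- 10
  expect_equal(system_suitability(ident)$rsd_area_pct, 0)
  expect_error(system_suitability(reps[1, ]), "2 replicates")

  off <- reps; off$observed_mz <- theo * (1 + 3e-6)
  expect_false(system_suitability(off)$mass_ok)
})
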