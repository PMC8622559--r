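nias_row <- function(migration, class = "I", compound = "X") {
  data.frame(compound = compound, cas = "0-0-0",
             migration_mg_kg = migration, ias = FALSE,
             sml_mg_kg = NA_real_, sml_no_limit = FALSE,
             cramer_class = class, stringsAsFactors = FALSE)
}

test_that("Cramer-class TDI lookup is exact and rejects unknown classes", {
  expect_identical(tdi_for_class("I"), 1.80)
  expect_identical(tdi_for_class("II"), 0.54)
  expect_identical(tdi_for_class("III"), 0.09)
  expect_identical(tdi_for_class(c("I", "III")), c(1.80, 0.09))
  expect_error(tdi_for_class("IV"), "IV")
})

test_that("EDI equals migration times the daily food intake", {
  expect_identical(edi(0.058), 0.058)
  expect_identical(edi(0), 0)
  expect_equal(edi(0.02, daily_food_intake = 2), 0.04)
  expect_error(edi(-1), "non-negative")
})

test_that("the consideration cut-off is strictly 'over 0.00015'", {
  at <- screen_risk(nias_row(0.00015))
  expect_false(at$considered)
  expect_identical(at$verdict, "excluded_below_threshold")
  above <- screen_risk(nias_row(0.00015 + 1e-9))
  expect_true(above$considered)
  expect_identical(above$verdict, "pass")
})

test_that("NIAS verdicts compare EDI to TDI and are monotone in migration", {
  pass <- screen_risk(nias_row(0.033, "III"))
  expect_equal(pass$edi, 0.033)
  expect_equal(pass$tdi, 0.09)
  expect_identical(pass$verdict, "pass")
  exceed <- screen_risk(nias_row(0.5, "III"))
  expect_identical(exceed$verdict, "exceed")
  # monotone: once exceeding, higher migration still exceeds
  for (m in c(0.09, 0.1, 1, 10)) {
    expect_identical(screen_risk(nias_row(m + 1e-9, "III"))$verdict, "exceed")
  }
  expect_error(screen_risk(nias_row(0.01, NA)), "Cramer")
})

test_that("IAS verdicts compare migration to SML, honouring 'no SML listed'", {
  ias <- nias_row(0.010); ias$ias <- TRUE; ias$cramer_class <- NA
  ias$sml_mg_kg <- 3
  r <- screen_risk(ias)
  expect_identical(r$verdict, "pass")
  expect_true(is.na(r$edi))  # IAS are not TTC-screened
  ias$sml_mg_kg <- 0.005
  expect_identical(screen_risk(ias)$verdict, "exceed")
  ias$sml_mg_kg <- NA; ias$sml_no_limit <- TRUE
  nol <- screen_risk(ias)
  expect_identical(nol$verdict, "pass")
  expect_match(nol$note, "no SML")
})

test_that("functional-barrier flag uses printed precision", {
  r1 <- screen_risk(nias_row(0.010))
  expect_true(r1$above_functional_barrier)
  r2 <- screen_risk(nias_row(0.0096))  # rounds to 0.010 at 3 decimals
  expect_true(r2$above_functional_barrier)
  r3 <- screen_risk(nias_row(0.009))
  expect_false(r3$above_functional_barrier)
})

test_that("the packaged case-study screen reproduces the reported funnel", {
  screened <- screen_risk(ldpe_screen_input())
  rep <- risk_report(screened)
  expect_identical(rep$summary$n_input, 83L)
  expect_identical(rep$summary$n_considered, 45L)
  expect_identical(rep$summary$n_above_functional_barrier, 9L)
  expect_identical(rep$summary$n_exceedances, 0L)
  # report is sorted by migration descending and round-trips through CSV
  expect_true(all(diff(rep$table$migration_mg_kg) <= 0))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep$table, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$migration_mg_kg, rep$table$migration_mg_kg)
  expect_identical(back$verdict, rep$table$verdict)
})

test_that("empty input yields zero counts", {
  rep <- risk_report(screen_risk(nias_row(1)[0, ]))
  expect_identical(rep$summary$n_considered, 0L)
  expect_identical(rep$summary$n_exceedances, 0L)
})
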