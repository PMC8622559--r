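test_that("the identification gate applies its printed criteria strictly", {
  cfg <- gate_config()
  # passing profile: high score, 3 fragments, small delta RI
  ok <- apply_gate(fake_match(97.0, 3, FALSE, dri = 9), cfg)
  expect_identical(ok$status, "identified")
  expect_length(ok$failed_criteria, 0L)
  # exactly at the score threshold is rejected
  expect_identical(apply_gate(fake_match(90, 3, TRUE, dri = 0), cfg)$status,
                   "rejected")
  expect_identical(apply_gate(fake_match(89.9, 3, TRUE, dri = 0),
                              cfg)$failed_criteria, "total_score")
  # exactly at the RI threshold is rejected
  expect_identical(apply_gate(fake_match(95, 3, FALSE, dri = 50),
                              cfg)$failed_criteria, "delta_ri")
  # 2 fragments + molecular ion passes; 2 fragments alone does not
  expect_identical(apply_gate(fake_match(95, 2, TRUE), cfg)$status,
                   "identified")
  expect_identical(apply_gate(fake_match(95, 2, FALSE), cfg)$failed_criteria,
                   "fragments")
  # absent delta RI is vacuous
  expect_identical(apply_gate(fake_match(95, 3, FALSE, dri = NA), cfg)$status,
                   "identified")
})

test_that("tightening any gate threshold never enlarges the identified set", {
  set.seed(51)
  n <- 300
  ms <- lapply(seq_len(n), function(i) {
    fake_match(runif(1, 80, 100), sample(0:6, 1), runif(1) < 0.5,
               dri = if (runif(1) < 0.2) NA_real_ else runif(1, 0, 80))
  })
  base <- gate_config()
  idset <- function(cfg) {
    which(vapply(ms, function(m) apply_gate(m, cfg)$status == "identified",
                 logical(1)))
  }
  s0 <- idset(base)
  tighter <- list(
    gate_config(min_total_score = 95),
    gate_config(max_delta_ri = 20),
    gate_config(min_annotated_fragments = 4L, fragments_with_molion = 3L),
    gate_config(min_total_score = 92, max_delta_ri = 30)
  )
  for (cfg in tighter) expect_true(all(idset(cfg) %in% s0))
})

test_that("IAS flagging marks Union-list CAS numbers and attaches SMLs", {
  ids <- ldpe_identified()
  flagged <- flag_ias(ids[, c("compound", "cas")], union_list_subset())
  expect_identical(sum(flagged$ias), 12L)
  expect_equal(flagged$sml_mg_kg[flagged$cas == "128-37-0"], 3)
  expect_false(flagged$ias[flagged$cas == "112-39-0"])
  expect_true(flagged$sml_no_limit[flagged$cas == "31570-04-4"])
  # a missing CAS is never flagged, with a warning
  with_missing <- rbind(flagged[1:2, c("compound", "cas")],
                        data.frame(compound = "Unknown", cas = NA))
  expect_warning(out <- flag_ias(with_missing, union_list_subset()), "CAS")
  expect_false(out$ias[3])
})

test_that("identification table reports planted compounds and no decoys", {
  sm <- small_sim()
  tab <- build_identification_table(sm$sim$features, sm$lib$records,
                                    sm$sim$ladder)
  expect_setequal(tab$compound, sm$lib$truth$compound)
  expect_false(any(grepl("DECOY", tab$compound)))
  expect_true(all(tab$n_replicates == 3L))
  expect_true(all(tab$total_score > 90))
  # empty input gives an empty, well-formed table
  empty <- build_identification_table(list(), sm$lib$records, sm$sim$ladder)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("compound", "total_score", "status") %in% names(empty)))
})

test_that("identification tables are deterministic across repeated runs", {
  sm <- small_sim()
  t1 <- build_identification_table(sm$sim$features, sm$lib$records,
                                   sm$sim$ladder)
  t2 <- build_identification_table(sm$sim$features, sm$lib$records,
                                   sm$sim$ladder)
  expect_identical(t1, t2)
})
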