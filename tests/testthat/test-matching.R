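test_that("SI score: self-similarity 100, disjoint spectra 0", {
  s <- ei_spectrum(c(41, 55, 91), c(100, 50, 999))
  expect_equal(si_score(s, s), 100)
  t <- ei_spectrum(c(43, 57, 93), c(100, 50, 999))
  expect_equal(si_score(s, t), 0)
})

test_that("SI score matches a hand evaluation of the composite formula", {
  q <- ei_spectrum(c(100, 200, 300), c(50, 100, 80))
  l <- ei_spectrum(c(100, 200, 250), c(50, 100, 60))
  # independent arithmetic: weights I^0.6 * mz^3, cos^2 dot over the two
  # shared peaks, ratio term over consecutive shared-peak intensity ratios
  w <- function(i, m) i^0.6 * m^3
  wq <- w(c(50, 100, 80), c(100, 200, 300))
  wl <- w(c(50, 100, 60), c(100, 200, 250))
  dot <- (wq[1] * wl[1] + wq[2] * wl[2])^2 / (sum(wq^2) * sum(wl^2))
  r <- (100 / 50) * (50 / 100)  # = 1
  expected <- 100 * (3 * dot + 2 * ((1 + r) / 2)) / (3 + 2)
  expect_equal(si_score(q, l), expected, tolerance = 1e-12)
})

test_that("SI score is invariant under uniform intensity scaling", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    q <- ei_spectrum(sort(runif(n, 40, 500)), runif(n, 1, 1000))
    l <- ei_spectrum(q$mz + runif(n, -0.002, 0.002), runif(n, 1, 1000))
    s0 <- si_score(q, l)
    q2 <- ei_spectrum(q$mz, q$intensity * 37.5)
    l2 <- ei_spectrum(l$mz, l$intensity * 0.004)
    expect_equal(si_score(q2, l2), s0, tolerance = 1e-9)
  }
})

test_that("subformula enumeration: parent reachable, unreachable empty, oracle agreement", {
  m_ch4 <- monoisotopic_mass("CH4", as_radical_cation = TRUE)
  hit <- enumerate_subformulas("CH4", m_ch4, 2)
  expect_identical(hit$formula, "CH4")
  expect_identical(nrow(enumerate_subformulas("CH4", 100.0, 2)), 0L)

  m_c4h9 <- monoisotopic_mass("C4H9", as_radical_cation = TRUE)
  res <- enumerate_subformulas("C15H24O", m_c4h9, 2)
  expect_true("C4H9" %in% res$formula)
  oracle <- brute_subformulas(c(C = 15, H = 24, O = 1), m_c4h9, 2)
  expect_setequal(res$formula, oracle)
})

test_that("enumeration results are ordered by |ppm| and respect the atom cap", {
  target <- monoisotopic_mass("C5H10", as_radical_cation = TRUE)
  res <- enumerate_subformulas("C20H42O2", target, 50)
  expect_true(all(diff(abs(res$delta_ppm)) >= -1e-12))
  big <- elemental_formula(c(C = 100, H = 100))
  expect_error(enumerate_subformulas(big, 100, 2), "120-atom")
})

test_that("HRF score: fully explained 100, unexplainable 0, partial per definition", {
  full <- bht_like_spectrum()
  expect_equal(hrf_score(full, "C15H24O"), 100)
  off <- ei_spectrum(full$mz + 0.05, full$intensity)
  expect_equal(hrf_score(off, "C15H24O"), 0)
  # 2 of 3 equal-intensity peaks assignable -> 66.7
  part <- ei_spectrum(c(full$mz[1], full$mz[2], full$mz[3] + 0.05),
                      c(100, 100, 100))
  expect_equal(hrf_score(part, "C15H24O"), 200 / 3, tolerance = 1e-9)
})

test_that("HRF score is monotone non-decreasing in tol_ppm", {
  set.seed(21)
  f <- parse_formula("C17H24O3")
  for (i in 1:5) {
    n <- 8
    s <- ei_spectrum(sort(runif(n, 40, 320)), runif(n, 1, 100))
    scores <- vapply(c(0.5, 1, 2, 5, 20, 100), function(tol) {
      hrf_score(s, f, tol_ppm = tol)
    }, numeric(1))
    expect_true(all(diff(scores) >= -1e-9))
  }
})

test_that("total score combines SI and HRF and degenerates to SI-only", {
  expect_equal(as.numeric(total_score(100, 100)), 100)
  expect_equal(as.numeric(total_score(96, 98)), 97)
  t <- total_score(90, NA_real_)
  expect_equal(as.numeric(t), 90)
  expect_true(attr(t, "si_only"))
  expect_error(total_score(50, 50, weights = c(0.7, 0.6)), "sum to 1")
})

test_that("fragment annotation finds exact subformula masses and the molecular ion", {
  ann <- annotate_fragments(bht_like_spectrum(), "C15H24O", tol_ppm = 2)
  expect_true(attr(ann, "molecular_ion_observed"))
  expect_gte(sum(ann$within_tol), 3L)
  expect_true(all(abs(ann$delta_ppm[ann$within_tol]) < 2))
  expect_true(any(ann$is_molecular_ion))

  shifted <- ei_spectrum(bht_like_spectrum()$mz * (1 + 10e-6),
                         bht_like_spectrum()$intensity)
  ann2 <- annotate_fragments(shifted, "C15H24O", tol_ppm = 2)
  expect_identical(sum(ann2$within_tol), 0L)
  expect_false(attr(ann2, "molecular_ion_observed"))
})

test_that("each peak is assigned its lowest-|ppm| subformula", {
  # a peak close to C4H9 but inside a wide window that also contains other
  # subformulas must still be assigned C4H9
  mz <- monoisotopic_mass("C4H9", as_radical_cation = TRUE) * (1 + 0.3e-6)
  ann <- annotate_fragments(ei_spectrum(c(mz, 41, 43), c(100, 10, 10)),
                            "C15H24O", tol_ppm = 2, top_n = 3)
  top <- ann[ann$intensity == 100, ]
  expect_identical(top$formula, "C4H9")
  expect_lt(abs(top$delta_ppm), 0.31)
  cands <- enumerate_subformulas("C15H24O", mz, 1e4)
  expect_identical(cands$formula[1], "C4H9")  # best-first ordering
  # repeated annotation is deterministic
  expect_identical(ann, annotate_fragments(
    ei_spectrum(c(mz, 41, 43), c(100, 10, 10)), "C15H24O",
    tol_ppm = 2, top_n = 3))
})

test_that("scores stay within [0, 100] under fuzzing", {
  set.seed(31)
  f <- parse_formula("C14H22O")
  for (i in 1:25) {
    n <- sample(2:15, 1)
    q <- ei_spectrum(sort(runif(n, 40, 500)), runif(n, 0.01, 1000))
    l <- ei_spectrum(sort(runif(n, 40, 500)), runif(n, 0.01, 1000))
    s <- si_score(q, l)
    h <- hrf_score(q, f, tol_ppm = runif(1, 0.5, 50))
    expect_gte(s, 0); expect_lte(s, 100)
    expect_gte(h, 0); expect_lte(h, 100)
  }
})

test_that("rank_candidates puts the true record first and orders ties deterministically", {
  sm <- small_sim()
  lib <- sm$lib$records
  ft <- Filter(function(f) f$feature_id == "P002" && f$replicate_id == "R1",
               sm$sim$features)[[1]]
  ranked <- rank_candidates(ft, lib, calculated_ri = compute_ri(ft$rt, sm$sim$ladder))
  expect_identical(ranked[[1]]$record$name, sm$lib$truth$compound[2])
  expect_gt(ranked[[1]]$total_score, 90)

  # equal-total tie: two identical records, order fixed by name
  s <- ei_spectrum(c(41, 55), c(10, 20))
  recs <- list(library_record("Bravo", s, formula = "C4H8"),
               library_record("Alpha", s, formula = "C4H8"))
  ft2 <- ms_feature("T", rt = 5, area = 1, spectrum = s)
  r2 <- rank_candidates(ft2, recs)
  expect_identical(vapply(r2, function(x) x$record$name, character(1)),
                   c("Alpha", "Bravo"))
})
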