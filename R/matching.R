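# Spectral library matching for EI spectra.
#
# Two complementary scores are combined. The search index (SI) is the
# Stein-Scott composite similarity: a weighted dot product with weights
# intensity^0.6 * mz^3 plus a paired-peak intensity-ratio term, scaled to
# 0-100. The high-resolution filtering (HRF) score is the fraction of
# spectral intensity explainable by exact-mass subformulas of the candidate
# molecular formula (EI fragments are treated as cations, so subformula
# theoretical m/z carries the electron-mass correction). The total score is
# a configurable weighted mean of the two.

#' Matching configuration
#'
#' @param mz_tol peak-pairing tolerance for the SI dot product, Th
#'   (default 0.005, suited to high-resolution centroids).
#' @param tol_ppm exact-mass tolerance for fragment/subformula annotation,
#'   ppm (default 2).
#' @param weights length-2 numeric `c(si, hrf)` summing to 1.
#' @param top_n number of most intense query peaks submitted to fragment
#'   annotation (default 10, minimum 3).
#' @param intensity_floor HRF intensity floor as a fraction of the base
#'   peak (default 0.001, i.e. 0.1%).
#' @return list of class `match_config`.
#' @export
match_config <- function(mz_tol = 0.005, tol_ppm = 2,
                         weights = c(si = 0.5, hrf = 0.5),
                         top_n = 10L, intensity_floor = 0.001) {
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("score weights must sum to 1 (got ", sum(weights), ")")
  }
  if (top_n < 3L) stop("top_n must be at least 3")
  stopifnot(mz_tol > 0, tol_ppm > 0, intensity_floor >= 0)
  structure(list(mz_tol = mz_tol, tol_ppm = tol_ppm,
                 weights = unname(weights), top_n = as.integer(top_n),
                 intensity_floor = intensity_floor),
            class = "match_config")
}

# Greedy peak pairing by smallest |delta mz| within tolerance; each peak of
# either spectrum is used at most once. Symmetric under argument exchange.
pair_peaks <- function(mz_a, mz_b, mz_tol) {
  cand_a <- integer(0); cand_b <- integer(0); d <- numeric(0)
  lo <- findInterval(mz_a - mz_tol, mz_b)
  hi <- findInterval(mz_a + mz_tol, mz_b)
  for (i in seq_along(mz_a)) {
    if (hi[i] > lo[i]) {
      j <- (lo[i] + 1L):hi[i]
      cand_a <- c(cand_a, rep.int(i, length(j)))
      cand_b <- c(cand_b, j)
      d <- c(d, abs(mz_a[i] - mz_b[j]))
    }
  }
  if (length(d) == 0L) return(cbind(a = integer(0), b = integer(0)))
  o <- order(d, cand_a, cand_b)
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep_a <- integer(0); keep_b <- integer(0)
  for (k in o) {
    i <- cand_a[k]; j <- cand_b[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      keep_a <- c(keep_a, i); keep_b <- c(keep_b, j)
    }
  }
  cbind(a = keep_a, b = keep_b)
}

#' Search-index (SI) spectral similarity
#'
#' Stein-Scott composite similarity between a query and a library EI
#' spectrum, on a 0-100 scale. Peaks are paired greedily within `mz_tol`;
#' the weighted-dot-product term uses weight vectors
#' `intensity^0.6 * mz^3`, and the composite adds the paired-peak
#' intensity-ratio term averaged with weights equal to the peak counts.
#' Invariant under uniform intensity scaling of either spectrum.
#'
#' @param query,library [ei_spectrum()] objects.
#' @param mz_tol pairing tolerance in Th.
#' @return similarity score in [0, 100].
#' @export
si_score <- function(query, library, mz_tol = 0.005) {
  stopifnot(is_spectrum(query), is_spectrum(library))
  if (sum(query$intensity) == 0 || sum(library$intensity) == 0) {
    stop("cannot score an all-zero-intensity spectrum")
  }
  wq <- query$intensity^0.6 * query$mz^3
  wl <- library$intensity^0.6 * library$mz^3
  pairs <- pair_peaks(query$mz, library$mz, mz_tol)
  n_pair <- nrow(pairs)
  if (n_pair == 0L) return(0)
  dot <- sum(wq[pairs[, "a"]] * wl[pairs[, "b"]])^2 /
    (sum(wq^2) * sum(wl^2))
  nq <- nrow(query)
  if (n_pair > 1L) {
    # consecutive paired-peak intensity ratios, exponent chosen so each
    # term is <= 1
    o <- order(query$mz[pairs[, "a"]])
    iq <- query$intensity[pairs[o, "a"]]
    il <- library$intensity[pairs[o, "b"]]
    r <- (iq[-1] / iq[-n_pair]) * (il[-n_pair] / il[-1])
    r[r > 1] <- 1 / r[r > 1]
    f_ratio <- (1 + sum(r)) / n_pair
    score <- (nq * dot + n_pair * f_ratio) / (nq + n_pair)
  } else {
    score <- dot
  }
  100 * max(0, min(1, score))
}

# --- subformula machinery ---------------------------------------------------

# Enumerate every subformula mass of a parent formula (excluding the empty
# formula): a vector of radical-cation masses plus the atom-count matrix,
# both in one fixed enumeration order. Parents are capped at 120 atoms
# (subformula count is a product of per-element counts and becomes
# combinatorial beyond that).
subformula_table <- function(parent) {
  stopifnot(inherits(parent, "elemental_formula"))
  if (n_atoms(parent) > 120L) {
    stop("parent formula ", format(parent), " exceeds the 120-atom cap ",
         "for exhaustive subformula enumeration")
  }
  key <- format(parent)
  cached <- .subformula_cache[[key]]
  if (!is.null(cached)) return(cached)
  syms <- names(parent$counts)
  masses <- 0
  counts <- matrix(0L, nrow = 1L, ncol = length(syms),
                   dimnames = list(NULL, syms))
  for (e in syms) {
    n <- parent$counts[[e]]
    step <- (0:n) * .ISOTOPE_MASS[[e]]
    k <- nrow(counts)
    masses <- rep(masses, times = n + 1L) + rep(step, each = k)
    counts <- counts[rep(seq_len(k), times = n + 1L), , drop = FALSE]
    counts[, e] <- rep(0:n, each = k)
  }
  keep <- rowSums(counts) > 0L
  masses <- masses[keep] - .ELECTRON_MASS  # cation convention
  counts <- counts[keep, , drop = FALSE]
  o <- order(masses)
  out <- list(mass = masses[o], counts = counts[o, , drop = FALSE],
              n_hetero = rowSums(counts[o, !syms %in% c("C", "H"),
                                        drop = FALSE]))
  .subformula_cache[[key]] <- out
  out
}

.subformula_cache <- new.env(parent = emptyenv())

#' Enumerate subformulas matching a target m/z
#'
#' All formulas elementwise between the empty formula (exclusive) and
#' `parent` (inclusive) whose radical-cation mass lies within `tol_ppm` of
#' `target_mz`, ordered by increasing |mass error|, ties broken by fewer
#' heteroatoms.
#'
#' @param parent candidate molecular formula ([elemental_formula()] or
#'   string).
#' @param target_mz observed fragment m/z (Th).
#' @param tol_ppm mass tolerance in ppm.
#' @return data.frame with columns `formula`, `theoretical_mz`,
#'   `delta_ppm`; zero rows when nothing matches.
#' @export
enumerate_subformulas <- function(parent, target_mz, tol_ppm = 2) {
  if (is.character(parent)) parent <- parse_formula(parent)
  stopifnot(target_mz > 0, tol_ppm > 0)
  tab <- subformula_table(parent)
  lo <- target_mz * (1 - tol_ppm * 1e-6)
  hi <- target_mz * (1 + tol_ppm * 1e-6)
  idx <- which(tab$mass >= lo & tab$mass <= hi)
  if (length(idx) == 0L) {
    return(data.frame(formula = character(0), theoretical_mz = numeric(0),
                      delta_ppm = numeric(0)))
  }
  dppm <- ppm_error(target_mz, tab$mass[idx])
  o <- order(abs(dppm), tab$n_hetero[idx])
  idx <- idx[o]
  fml <- apply(tab$counts[idx, , drop = FALSE], 1L, function(cc) {
    format(elemental_formula(cc[cc > 0]))
  })
  data.frame(formula = unname(fml), theoretical_mz = tab$mass[idx],
             delta_ppm = dppm[o])
}

#' High-resolution filtering (HRF) score
#'
#' Fraction of spectral intensity explainable by exact-mass subformulas of
#' the candidate molecular formula, on a 0-100 scale. Peaks below the
#' intensity floor (fraction of base peak) are excluded from both
#' numerator and denominator.
#'
#' @param query an [ei_spectrum()].
#' @param candidate_formula [elemental_formula()] or string.
#' @param tol_ppm annotation tolerance, ppm.
#' @param intensity_floor fraction of base-peak intensity below which peaks
#'   are ignored (default 0.001).
#' @return score in [0, 100].
#' @export
hrf_score <- function(query, candidate_formula, tol_ppm = 2,
                      intensity_floor = 0.001) {
  stopifnot(is_spectrum(query))
  if (is.character(candidate_formula)) {
    candidate_formula <- parse_formula(candidate_formula)
  }
  if (all(query$intensity == 0)) stop("all-zero-intensity spectrum")
  tab <- subformula_table(candidate_formula)
  floor_abs <- intensity_floor * base_peak_intensity(query)
  keep <- query$intensity >= floor_abs & query$intensity > 0
  mz <- query$mz[keep]
  inten <- query$intensity[keep]
  lo <- findInterval(mz * (1 - tol_ppm * 1e-6), tab$mass)
  hi <- findInterval(mz * (1 + tol_ppm * 1e-6), tab$mass)
  explained <- hi > lo
  min(100, 100 * sum(inten[explained]) / sum(inten))
}

#' Composite total score
#'
#' Weighted arithmetic mean of the SI and HRF scores. When the HRF score is
#' unavailable (candidate without a molecular formula) the total degenerates
#' to the SI score and is flagged `si_only`.
#'
#' @param si SI score in [0, 100].
#' @param hrf HRF score in [0, 100], or `NA` when unavailable.
#' @param weights length-2 numeric `c(si, hrf)` summing to 1.
#' @return total score in [0, 100]; attribute `si_only` is `TRUE` when the
#'   HRF contribution was unavailable.
#' @export
total_score <- function(si, hrf, weights = c(0.5, 0.5)) {
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("score weights must sum to 1 (got ", sum(weights), ")")
  }
  stopifnot(si >= 0, si <= 100)
  if (is.na(hrf)) return(structure(si, si_only = TRUE))
  stopifnot(hrf >= 0, hrf <= 100)
  structure(weights[1] * si + weights[2] * hrf, si_only = FALSE)
}

#' Annotate fragment ions with exact-mass subformulas
#'
#' Annotates the `top_n` most intense query peaks with their best
#' (lowest |ppm error|) subformula of the candidate molecular formula.
#' Every top peak receives its nearest subformula (error recorded as
#' computed, without clipping); the `within_tol` column marks those inside
#' `tol_ppm`. A peak equidistant from two subformulas is assigned the one
#' with fewer heteroatoms; all tied alternatives are kept in the `ties`
#' attribute for diagnostics.
#'
#' @param query an [ei_spectrum()].
#' @param candidate_formula [elemental_formula()] or string.
#' @param tol_ppm annotation tolerance, ppm (default 2).
#' @param top_n number of most intense peaks to annotate (minimum 3).
#' @return data.frame of class `fragment_annotations` with columns `mz`,
#'   `intensity`, `formula`, `theoretical_mz`, `delta_ppm`, `within_tol`,
#'   `is_molecular_ion`; attributes `molecular_ion_observed` (flag) and
#'   `ties` (diagnostics).
#' @export
annotate_fragments <- function(query, candidate_formula, tol_ppm = 2,
                               top_n = 10L) {
  stopifnot(is_spectrum(query))
  if (top_n < 3L) stop("top_n must be at least 3")
  if (is.character(candidate_formula)) {
    candidate_formula <- parse_formula(candidate_formula)
  }
  tab <- subformula_table(candidate_formula)
  mion_mz <- monoisotopic_mass(candidate_formula, as_radical_cation = TRUE)
  mion_observed <- any(abs(ppm_error(query$mz, mion_mz)) <= tol_ppm)

  o <- order(-query$intensity, query$mz)
  o <- o[seq_len(min(top_n, length(o)))]
  ties <- list()
  rows <- lapply(o, function(i) {
    mz_i <- query$mz[i]
    j <- findInterval(mz_i, tab$mass)
    cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(tab$mass)))
    dppm <- ppm_error(mz_i, tab$mass[cand])
    best_abs <- min(abs(dppm))
    tied <- cand[abs(abs(dppm) - best_abs) < 1e-12]
    if (length(tied) > 1L) {
      tied <- tied[order(tab$n_hetero[tied])]
      ties[[length(ties) + 1L]] <<- data.frame(
        mz = mz_i,
        formula = vapply(tied, function(k) {
          cc <- tab$counts[k, ]
          format(elemental_formula(cc[cc > 0]))
        }, character(1)),
        delta_ppm = ppm_error(mz_i, tab$mass[tied])
      )
    }
    k <- tied[1L]
    cc <- tab$counts[k, ]
    data.frame(
      mz = mz_i, intensity = query$intensity[i],
      formula = format(elemental_formula(cc[cc > 0])),
      theoretical_mz = tab$mass[k],
      delta_ppm = ppm_error(mz_i, tab$mass[k]),
      within_tol = abs(ppm_error(mz_i, tab$mass[k])) <= tol_ppm,
      is_molecular_ion = abs(ppm_error(mz_i, mion_mz)) <= tol_ppm
    )
  })
  ann <- do.call(rbind, rows)
  structure(ann,
            class = c("fragment_annotations", "data.frame"),
            molecular_ion_observed = mion_observed,
            ties = if (length(ties)) do.call(rbind, ties) else NULL)
}

#' Score and rank library candidates for one feature
#'
#' Computes the SI, HRF and total score of every library record against the
#' feature's spectrum, annotates fragments, and returns candidates sorted
#' by total score (ties: more fragments within tolerance first, then
#' smaller |delta RI|, then name). Records without a molecular formula are
#' scored SI-only and carry no fragment annotations. A candidate from a
#' local mass list (source tag containing "masslist") whose molecular ion
#' is observed is flagged `mass_list_hit` as corroborating evidence.
#'
#' @param feature an [ms_feature()].
#' @param library list of [library_record()].
#' @param config a [match_config()].
#' @param calculated_ri the feature's retention index (an `ri_value` from
#'   [compute_ri()] or a bare number), or `NA` to skip delta-RI.
#' @return list of `match_result` objects, best first.
#' @export
rank_candidates <- function(feature, library, config = match_config(),
                            calculated_ri = NA_real_) {
  stopifnot(inherits(feature, "ms_feature"), length(library) > 0L)
  ri <- if (inherits(calculated_ri, "ri_value")) calculated_ri$ri
        else as.numeric(calculated_ri)
  results <- lapply(library, function(rec) {
    si <- si_score(feature$spectrum, rec$spectrum, config$mz_tol)
    if (!is.null(rec$formula)) {
      hrf <- hrf_score(feature$spectrum, rec$formula, config$tol_ppm,
                       config$intensity_floor)
      ann <- annotate_fragments(feature$spectrum, rec$formula,
                                config$tol_ppm, config$top_n)
      n_tol <- sum(ann$within_tol)
      mion <- attr(ann, "molecular_ion_observed")
    } else {
      hrf <- NA_real_; ann <- NULL; n_tol <- 0L; mion <- FALSE
    }
    tot <- total_score(si, hrf, config$weights)
    dri <- if (!is.na(ri) && !is.na(rec$library_ri)) abs(ri - rec$library_ri)
           else NA_real_
    structure(
      list(record = rec, si_score = si, hrf_score = hrf,
           total_score = as.numeric(tot), si_only = isTRUE(attr(tot, "si_only")),
           annotations = ann, n_fragments_within_tol = n_tol,
           molecular_ion_observed = mion, delta_ri = dri,
           mass_list_hit = mion &&
             grepl("masslist", rec$source_tag %||% "", ignore.case = TRUE)),
      class = "match_result"
    )
  })
  ord <- order(
    -vapply(results, `[[`, numeric(1), "total_score"),
    -vapply(results, function(r) as.numeric(r$n_fragments_within_tol),
            numeric(1)),
    vapply(results, function(r) if (is.na(r$delta_ri)) Inf else r$delta_ri,
           numeric(1)),
    vapply(results, function(r) r$record$name, character(1))
  )
  results[ord]
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %s: total %.1f (SI %.1f, HRF %s)%s, %d frag <tol, M+. %s, dRI %s\n",
    x$record$name, x$total_score, x$si_score,
    if (is.na(x$hrf_score)) "-" else sprintf("%.1f", x$hrf_score),
    if (x$si_only) " [SI-only]" else "",
    x$n_fragments_within_tol, if (x$molecular_ion_observed) "yes" else "no",
    if (is.na(x$delta_ri)) "-" else sprintf("%.0f", x$delta_ri)))
  invisible(x)
}

#' Flatten match results to a data.frame
#'
#' @param results list of `match_result` (as returned by
#'   [rank_candidates()]).
#' @return data.frame with one row per candidate.
#' @export
match_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      candidate = r$record$name, cas = r$record$cas,
      formula = if (is.null(r$record$formula)) NA_character_
                else format(r$record$formula),
      si_score = r$si_score, hrf_score = r$hrf_score,
      total_score = r$total_score, si_only = r$si_only,
      n_fragments_within_tol = r$n_fragments_within_tol,
      molecular_ion_observed = r$molecular_ion_observed,
      delta_ri = r$delta_ri, mass_list_hit = r$mass_list_hit,
      stringsAsFactors = FALSE
    )
  }))
}
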