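# Identification gate and tiered identification table.
#
# A candidate is tentatively identified only under a restrictive set of
# criteria: composite library match (total score) above 90 (strict), exact
# mass accuracy below 2 ppm (strict) for at least 3 annotated fragments or
# 2 fragments plus the molecular ion when observed, and an absolute
# retention-index difference below 50 units (strict) whenever the library
# provides an RI (the criterion is vacuous when it does not).

#' Identification gate configuration
#'
#' All numeric thresholds are compared strictly, matching their printed
#' form (`>90`, `<2 ppm`, `<50`).
#'
#' @param min_total_score minimum composite score, exclusive (default 90).
#' @param max_delta_mass_ppm fragment mass-accuracy bound, ppm, exclusive
#'   (default 2).
#' @param min_annotated_fragments fragments within tolerance required
#'   without the molecular ion (default 3).
#' @param fragments_with_molion fragments required when the molecular ion
#'   is observed (default 2; must not exceed `min_annotated_fragments`).
#' @param max_delta_ri RI-difference bound, exclusive (default 50).
#' @param min_replicates replicates in which a compound must be identified
#'   to be reported (default 2; capped at the number of replicates present
#'   in the data).
#' @param ambiguity_margin two top candidates whose total scores differ by
#'   less than this are both reported as ambiguous (default 1).
#' @return list of class `gate_config`.
#' @export
gate_config <- function(min_total_score = 90, max_delta_mass_ppm = 2,
                        min_annotated_fragments = 3L,
                        fragments_with_molion = 2L,
                        max_delta_ri = 50, min_replicates = 2L,
                        ambiguity_margin = 1) {
  stopifnot(min_total_score > 0, max_delta_mass_ppm > 0, max_delta_ri > 0,
            min_annotated_fragments >= 1L, fragments_with_molion >= 1L,
            min_replicates >= 1L, ambiguity_margin >= 0)
  if (fragments_with_molion > min_annotated_fragments) {
    stop("fragments_with_molion must not exceed min_annotated_fragments")
  }
  structure(list(min_total_score = min_total_score,
                 max_delta_mass_ppm = max_delta_mass_ppm,
                 min_annotated_fragments = as.integer(min_annotated_fragments),
                 fragments_with_molion = as.integer(fragments_with_molion),
                 max_delta_ri = max_delta_ri,
                 min_replicates = as.integer(min_replicates),
                 ambiguity_margin = ambiguity_margin),
            class = "gate_config")
}

#' Apply the identification gate to one match result
#'
#' @param m a `match_result` (from [rank_candidates()]).
#' @param cfg a [gate_config()].
#' @return list with `status` (`"identified"` or `"rejected"`) and
#'   `failed_criteria` (character vector drawn from `"total_score"`,
#'   `"fragments"`, `"delta_ri"`; empty when identified).
#' @export
apply_gate <- function(m, cfg = gate_config()) {
  stopifnot(inherits(m, "match_result"), inherits(cfg, "gate_config"))
  failed <- character(0)
  if (!(m$total_score > cfg$min_total_score)) failed <- c(failed, "total_score")
  frag_ok <- m$n_fragments_within_tol >= cfg$min_annotated_fragments ||
    (m$n_fragments_within_tol >= cfg$fragments_with_molion &&
       isTRUE(m$molecular_ion_observed))
  if (!frag_ok) failed <- c(failed, "fragments")
  if (!is.na(m$delta_ri) && !(m$delta_ri < cfg$max_delta_ri)) {
    failed <- c(failed, "delta_ri")
  }
  list(status = if (length(failed) == 0L) "identified" else "rejected",
       failed_criteria = failed)
}

#' Flag authorized substances (IAS) against a Union-list subset
#'
#' Marks each identification whose CAS number appears in the authorized
#' (Union-list) table and attaches its specific migration limit where one
#' is listed. Rows without a CAS number are never flagged and raise a
#' warning.
#'
#' @param identifications data.frame with a `cas` column (e.g. from
#'   [build_identification_table()] or a packaged identification table).
#' @param union_list data.frame with columns `cas`, `sml_mg_kg` and
#'   `sml_no_limit` (see [read_annotations()]).
#' @return `identifications` with columns `ias`, `sml_mg_kg`,
#'   `sml_no_limit` added/overwritten.
#' @export
flag_ias <- function(identifications, union_list) {
  stopifnot(is.data.frame(identifications), "cas" %in% names(identifications))
  stopifnot("cas" %in% names(union_list))
  no_cas <- is.na(identifications$cas) | !nzchar(identifications$cas)
  if (any(no_cas)) {
    warning(sum(no_cas), " identification(s) lack a CAS number; ",
            "treated as not authorized")
  }
  idx <- match(identifications$cas, union_list$cas)
  idx[no_cas] <- NA_integer_
  identifications$ias <- !is.na(idx)
  identifications$sml_mg_kg <- if ("sml_mg_kg" %in% names(union_list)) {
    union_list$sml_mg_kg[idx]
  } else NA_real_
  identifications$sml_no_limit <- if ("sml_no_limit" %in% names(union_list)) {
    ifelse(is.na(idx), FALSE, union_list$sml_no_limit[idx] %in% TRUE)
  } else FALSE
  identifications
}

#' Build the tiered identification table
#'
#' Runs the full identification chain over a set of deconvoluted features:
#' retention-index calculation, candidate ranking, the identification gate,
#' ambiguity marking, and replicate merging. A compound is reported when it
#' is identified in at least `min_replicates` replicates (capped at the
#' number of replicates present); the best-scoring instance is kept and its
#' maximum total score reported. A feature whose top two candidates lie
#' within `ambiguity_margin` total-score points is reported `ambiguous`.
#'
#' @param features list of [ms_feature()] (typically all replicates).
#' @param library list of [library_record()].
#' @param ladder an [alkane_ladder()], or `NULL` to skip RI.
#' @param cfg a [gate_config()].
#' @param match_cfg a [match_config()].
#' @param union_list optional Union-list annotation table for IAS flagging.
#' @return data.frame with one row per reported compound: `compound`,
#'   `cas`, `formula`, `total_score` (max over replicates), `si_score`,
#'   `hrf_score`, `delta_ri`, `n_fragments_within_tol`,
#'   `molecular_ion_observed`, `mass_list_hit`, `status`, `n_replicates`,
#'   `feature_id`, `replicate_id`, `area`, `rt_min` (of the best-scoring
#'   instance) and, when `union_list` is given, `ias`/`sml_mg_kg`.
#' @export
build_identification_table <- function(features, library, ladder = NULL,
                                       cfg = gate_config(),
                                       match_cfg = match_config(),
                                       union_list = NULL) {
  empty <- data.frame(
    compound = character(0), cas = character(0), formula = character(0),
    total_score = numeric(0), si_score = numeric(0), hrf_score = numeric(0),
    delta_ri = numeric(0), n_fragments_within_tol = integer(0),
    molecular_ion_observed = logical(0), mass_list_hit = logical(0),
    status = character(0), n_replicates = integer(0),
    feature_id = character(0), replicate_id = character(0),
    area = numeric(0), rt_min = numeric(0), stringsAsFactors = FALSE
  )
  if (length(features) == 0L) return(empty)
  per_feature <- lapply(features, function(ft) {
    ri <- if (is.null(ladder)) NA_real_ else compute_ri(ft$rt, ladder)
    ranked <- rank_candidates(ft, library, match_cfg, calculated_ri = ri)
    best <- ranked[[1L]]
    gate <- apply_gate(best, cfg)
    status <- gate$status
    if (status == "identified" && length(ranked) > 1L) {
      runner <- ranked[[2L]]
      if (best$total_score - runner$total_score < cfg$ambiguity_margin &&
          apply_gate(runner, cfg)$status == "identified") {
        status <- "ambiguous"
      }
    }
    data.frame(
      compound = best$record$name, cas = best$record$cas,
      formula = if (is.null(best$record$formula)) NA_character_
                else format(best$record$formula),
      total_score = best$total_score, si_score = best$si_score,
      hrf_score = best$hrf_score, delta_ri = best$delta_ri,
      n_fragments_within_tol = best$n_fragments_within_tol,
      molecular_ion_observed = best$molecular_ion_observed,
      mass_list_hit = best$mass_list_hit,
      status = status, feature_id = ft$feature_id,
      replicate_id = ft$replicate_id, area = ft$area, rt_min = ft$rt,
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, per_feature)
  hits <- hits[hits$status %in% c("identified", "ambiguous"), , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  n_reps <- length(unique(vapply(features, `[[`, character(1), "replicate_id")))
  need <- min(cfg$min_replicates, n_reps)
  out <- do.call(rbind, lapply(split(hits, hits$compound), function(g) {
    if (length(unique(g$replicate_id)) < need) return(NULL)
    best <- g[order(-g$total_score, g$feature_id), ][1L, , drop = FALSE]
    best$total_score <- max(g$total_score)
    best$n_replicates <- length(unique(g$replicate_id))
    best
  }))
  if (is.null(out)) return(empty)
  out <- out[order(-out$total_score, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(union_list)) out <- flag_ias(out, union_list)
  out
}
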