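# End-to-end orchestration: features -> identification -> semi-quant ->
# risk screen, with per-stage counters (the identification funnel).

#' Run the full screening pipeline
#'
#' Chains the identification gate, internal-standard semi-quantification
#' and the TTC risk screen over a set of deconvoluted features.
#'
#' @param features list of [ms_feature()] (all replicates).
#' @param library list of [library_record()].
#' @param ladder an [alkane_ladder()] or `NULL`.
#' @param standards internal-standard table (see
#'   [read_internal_standards()]).
#' @param union_list Union-list annotation table (columns `cas`,
#'   `sml_mg_kg`, `sml_no_limit`), or `NULL` for no IAS flagging.
#' @param cramer annotation table with columns `cas`, `cramer_class`, or
#'   `NULL`.
#' @param default_cramer_class class assumed for considered NIAS lacking
#'   an annotation (`NULL`, the default, makes a missing class an error;
#'   `"III"` is the conservative choice for screening).
#' @param gate_cfg a [gate_config()].
#' @param match_cfg a [match_config()].
#' @param risk_cfg a [risk_config()].
#' @param geom an [extract_geometry()].
#' @return list with `identifications`, `quantified`, `risk` (screened
#'   records), `report` (risk table + summary) and `counters`
#'   (`n_features`, `n_identified`, `n_ias`, `n_considered`,
#'   `n_above_functional_barrier`, `n_exceedances`).
#' @export
run_screen <- function(features, library, ladder = NULL, standards,
                       union_list = NULL, cramer = NULL,
                       default_cramer_class = NULL,
                       gate_cfg = gate_config(),
                       match_cfg = match_config(),
                       risk_cfg = risk_config(),
                       geom = extract_geometry()) {
  ids <- build_identification_table(features, library, ladder,
                                    cfg = gate_cfg, match_cfg = match_cfg,
                                    union_list = union_list)
  if (is.null(union_list)) {
    ids$ias <- FALSE
    ids$sml_mg_kg <- NA_real_
    ids$sml_no_limit <- FALSE
  }
  quant <- semi_quantify(ids, standards, geom)
  quant$cramer_class <- if (!is.null(cramer)) {
    cramer$cramer_class[match(quant$cas, cramer$cas)]
  } else NA_character_
  if (!is.null(default_cramer_class)) {
    fill <- is.na(quant$cramer_class) & !quant$ias
    quant$cramer_class[fill] <- default_cramer_class
  }
  screened <- screen_risk(quant, risk_cfg)
  rep <- risk_report(screened)
  list(
    identifications = ids,
    quantified = quant,
    risk = screened,
    report = rep,
    counters = c(
      list(n_features = length(features), n_identified = nrow(ids),
           n_ias = sum(ids$ias %in% TRUE)),
      rep$summary[c("n_considered", "n_above_functional_barrier",
                    "n_exceedances")]
    )
  )
}
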