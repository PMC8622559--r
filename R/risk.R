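# TTC risk screen.
#
# Substances with an estimated migration at or below 0.00015 mg/kg (the
# migration ceiling applicable when genotoxicity has not been discarded)
# are excluded from assessment; the cut-off is strict ("over 0.00015").
# For considered NIAS the estimated daily intake (EDI, assuming 1 kg of
# packed food consumed per person per day) is compared against the
# Cramer-class tolerable daily intake (TDI); considered IAS are compared
# against their specific migration limit (SML) instead. NIAS at or above
# the 0.01 mg/kg functional-barrier ceiling are additionally flagged for
# reporting; that comparison is made at the report's printed precision.

.TDI_BY_CLASS <- c(I = 1.80, II = 0.54, III = 0.09)

#' Cramer-class tolerable daily intake
#'
#' TTC tier values: Class I (low hazard) 1.80, Class II (intermediate)
#' 0.54, Class III (high) 0.09 mg per person per day.
#'
#' @param cramer_class `"I"`, `"II"` or `"III"` (vectorised).
#' @return TDI in mg person^-1 day^-1.
#' @export
tdi_for_class <- function(cramer_class) {
  cramer_class <- as.character(cramer_class)
  bad <- !cramer_class %in% names(.TDI_BY_CLASS)
  if (any(bad)) {
    stop("unknown Cramer class: ", paste(unique(cramer_class[bad]), collapse = ", "))
  }
  unname(.TDI_BY_CLASS[cramer_class])
}

#' Estimated daily intake
#'
#' `EDI (mg person^-1 day^-1) = migration (mg/kg) x daily intake of packed
#' food (kg/day)`, with the European default assumption of 1 kg/day.
#'
#' @param migration estimated migration, mg/kg (>= 0, vectorised).
#' @param daily_food_intake kg of packed food per person per day.
#' @return EDI in mg person^-1 day^-1.
#' @export
edi <- function(migration, daily_food_intake = 1) {
  if (any(migration < 0)) stop("migration must be non-negative")
  stopifnot(daily_food_intake > 0)
  migration * daily_food_intake
}

#' Risk-screen configuration
#'
#' @param consideration_threshold migration above which a substance enters
#'   the assessment, mg/kg (default 0.00015; comparison strict).
#' @param functional_barrier_limit NIAS migration ceiling, mg/kg
#'   (default 0.01).
#' @param barrier_digits decimals to which migration is rounded before the
#'   functional-barrier comparison (default 3, the precision at which the
#'   limit itself is stated).
#' @param daily_food_intake kg of packed food per person per day
#'   (default 1).
#' @return list of class `risk_config`.
#' @export
risk_config <- function(consideration_threshold = 0.00015,
                        functional_barrier_limit = 0.01,
                        barrier_digits = 3L, daily_food_intake = 1) {
  stopifnot(consideration_threshold > 0, functional_barrier_limit > 0,
            barrier_digits >= 0, daily_food_intake > 0)
  structure(list(consideration_threshold = consideration_threshold,
                 functional_barrier_limit = functional_barrier_limit,
                 barrier_digits = as.integer(barrier_digits),
                 daily_food_intake = daily_food_intake),
            class = "risk_config")
}

#' TTC risk screen
#'
#' Screens identified substances with estimated migrations. Each record
#' receives a verdict: `excluded_below_threshold` (migration at or below
#' the consideration threshold), `pass`, or `exceed`. Considered NIAS
#' require a Cramer class (an error names any compound missing one) and
#' pass when EDI <= TDI; considered IAS pass when migration <= SML, or
#' unconditionally with a note when authorized without a listed SML.
#'
#' @param records data.frame with columns `compound`, `cas`,
#'   `migration_mg_kg`, `ias` (logical), `sml_mg_kg`, `sml_no_limit`
#'   (logical), `cramer_class` (`"I"/"II"/"III"` or `NA`).
#' @param cfg a [risk_config()].
#' @return data.frame of class `risk_records`: the input plus `considered`,
#'   `above_functional_barrier`, `tdi`, `edi`, `verdict`, `note`.
#' @export
screen_risk <- function(records, cfg = risk_config()) {
  stopifnot(inherits(cfg, "risk_config"))
  req <- c("compound", "migration_mg_kg", "ias")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("risk input missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"cramer_class" %in% names(records)) records$cramer_class <- NA_character_
  if (!"sml_mg_kg" %in% names(records)) records$sml_mg_kg <- NA_real_
  if (!"sml_no_limit" %in% names(records)) records$sml_no_limit <- FALSE
  if (!"cas" %in% names(records)) records$cas <- NA_character_
  if (any(records$migration_mg_kg < 0, na.rm = TRUE)) {
    stop("migration must be non-negative")
  }
  n <- nrow(records)
  records$considered <- records$migration_mg_kg > cfg$consideration_threshold
  records$above_functional_barrier <-
    round(records$migration_mg_kg, cfg$barrier_digits) >=
      cfg$functional_barrier_limit & records$considered
  records$tdi <- rep(NA_real_, n)
  records$edi <- rep(NA_real_, n)
  records$verdict <- rep("excluded_below_threshold", n)
  records$note <- rep("", n)
  for (i in seq_len(n)) {
    if (!records$considered[i]) next
    if (isTRUE(records$ias[i])) {
      # authorized substance: compare against its SML
      if (isTRUE(records$sml_no_limit[i])) {
        records$verdict[i] <- "pass"
        records$note[i] <- "authorized, no SML listed"
      } else if (is.na(records$sml_mg_kg[i])) {
        stop("considered IAS '", records$compound[i],
             "' has no SML entry (use '-' for authorized without SML)")
      } else {
        records$verdict[i] <-
          if (records$migration_mg_kg[i] <= records$sml_mg_kg[i]) "pass"
          else "exceed"
      }
    } else {
      if (is.na(records$cramer_class[i])) {
        stop("considered NIAS '", records$compound[i],
             "' lacks a Cramer class")
      }
      records$tdi[i] <- tdi_for_class(records$cramer_class[i])
      records$edi[i] <- edi(records$migration_mg_kg[i], cfg$daily_food_intake)
      records$verdict[i] <- if (records$edi[i] <= records$tdi[i]) "pass"
                            else "exceed"
      if (records$above_functional_barrier[i]) {
        records$note[i] <- "NIAS above functional-barrier limit"
      }
    }
  }
  class(records) <- c("risk_records", "data.frame")
  records
}

#' Risk-screen report and summary counts
#'
#' @param records screened records from [screen_risk()].
#' @return list with `table` (considered records sorted by migration
#'   descending) and `summary` (`n_input`, `n_considered`,
#'   `n_above_functional_barrier`, `n_exceedances`).
#' @export
risk_report <- function(records) {
  stopifnot(inherits(records, "risk_records"))
  tab <- records[records$considered, , drop = FALSE]
  tab <- tab[order(-tab$migration_mg_kg, tab$compound), , drop = FALSE]
  rownames(tab) <- NULL
  list(
    table = tab,
    summary = list(
      n_input = nrow(records),
      n_considered = sum(records$considered),
      n_above_functional_barrier = sum(records$above_functional_barrier),
      n_exceedances = sum(records$verdict == "exceed")
    )
  )
}
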