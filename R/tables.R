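# Packaged reference dataset: the tentative-identification and risk-screen
# tables from a published untargeted screen of a post-consumer recycled
# LDPE film, transcribed as plain CSV, plus the matching Union-list subset.
# Each accessor verifies the file checksum before parsing, so silent
# corruption of the packaged data is caught at load.

.LDPE_MD5 <- c(
  ldpe_identified.csv    = "cd117b5e8957f1e90aefa42db1a43b1a",
  ldpe_risk.csv          = "0d050d54e6509cd4ef208877323248ff",
  union_list_subset.csv  = "f17eea929e79272f971f8515287d6bae"
)

ldpe_file <- function(name) {
  path <- system.file("extdata", name, package = "fcmscreen", mustWork = TRUE)
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(.LDPE_MD5[[name]]))) {
    stop("packaged data file ", name, " failed its checksum (", got, ")")
  }
  path
}

#' Packaged LDPE case-study: tentatively identified substances
#'
#' The 83 substances tentatively identified in a triplicate screen of a
#' post-consumer recycled LDPE film, with CAS number, molecular formula,
#' composite library match score (%), absolute retention-index difference
#' (`NA` where the library held no RI) and Union-list membership.
#'
#' @return data.frame with columns `section`, `compound`, `cas`,
#'   `formula`, `total_score`, `delta_ri`, `ias`.
#' @export
ldpe_identified <- function() {
  tab <- utils::read.csv(ldpe_file("ldpe_identified.csv"),
                         stringsAsFactors = FALSE)
  tab$ias <- as.logical(tab$ias)
  tab
}

#' Packaged LDPE case-study: risk-screen table
#'
#' The substances from [ldpe_identified()] whose estimated migration
#' exceeded the 0.00015 mg/kg consideration threshold, with estimated
#' migration (and replicate half-width where determined with analytical
#' standards), specific migration limit for authorized substances
#' (`sml_no_limit` marks substances authorized without a listed SML),
#' Cramer class, TDI and EDI. Migration values are kept at their reported
#' precision.
#'
#' @return data.frame with columns `compound`, `cas`, `migration_mg_kg`,
#'   `migration_sd`, `sml_mg_kg`, `sml_no_limit`, `cramer_class`, `tdi`,
#'   `edi`, plus `migration_printed` (the value as reported, as text).
#' @export
ldpe_risk <- function() {
  tab <- utils::read.csv(ldpe_file("ldpe_risk.csv"),
                         stringsAsFactors = FALSE, colClasses = "character")
  out <- data.frame(
    compound = tab$compound, cas = tab$cas,
    migration_mg_kg = as.numeric(tab$migration),
    migration_printed = tab$migration,
    migration_sd = suppressWarnings(as.numeric(tab$migration_sd)),
    sml_mg_kg = suppressWarnings(as.numeric(tab$sml_mg_kg)),
    sml_no_limit = tab$sml_mg_kg == "-",
    cramer_class = ifelse(nzchar(tab$cramer_class), tab$cramer_class,
                          NA_character_),
    tdi = suppressWarnings(as.numeric(tab$tdi)),
    edi = suppressWarnings(as.numeric(tab$edi)),
    stringsAsFactors = FALSE
  )
  out
}

#' Packaged Union-list subset
#'
#' The authorized substances (IAS) among the packaged LDPE
#' identifications, keyed by CAS, with their specific migration limits
#' where listed (`-` in the source, i.e. authorized without an SML, is
#' exposed as `sml_no_limit = TRUE`; an empty entry means no SML was
#' transcribed).
#'
#' @return data.frame with columns `compound`, `cas`, `sml_mg_kg`,
#'   `sml_no_limit`.
#' @export
union_list_subset <- function() {
  tab <- utils::read.csv(ldpe_file("union_list_subset.csv"),
                         stringsAsFactors = FALSE, colClasses = "character")
  data.frame(
    compound = tab$compound, cas = tab$cas,
    sml_mg_kg = suppressWarnings(as.numeric(tab$sml_mg_kg)),
    sml_no_limit = tab$sml_mg_kg == "-",
    stringsAsFactors = FALSE
  )
}

#' Assemble the packaged case-study input for the risk screen
#'
#' Joins the identification table to the risk table: each of the 83
#' identified substances with its estimated migration (substances absent
#' from the risk table sat below the consideration threshold; their
#' unreported migrations are represented as 0), Union-list membership,
#' SML and Cramer class — the input contract of [screen_risk()].
#'
#' @return data.frame with columns `compound`, `cas`, `migration_mg_kg`,
#'   `ias`, `sml_mg_kg`, `sml_no_limit`, `cramer_class`.
#' @export
ldpe_screen_input <- function() {
  ids <- ldpe_identified()
  risk <- ldpe_risk()
  idx <- match(ids$cas, risk$cas)
  data.frame(
    compound = ids$compound, cas = ids$cas,
    migration_mg_kg = ifelse(is.na(idx), 0, risk$migration_mg_kg[idx]),
    ias = ids$ias,
    sml_mg_kg = risk$sml_mg_kg[idx],
    sml_no_limit = ifelse(is.na(idx), FALSE, risk$sml_no_limit[idx]),
    cramer_class = risk$cramer_class[idx],
    stringsAsFactors = FALSE
  )
}
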