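# CSV readers/writers for feature tables, alkane ladders, annotation
# tables and internal-standard definitions. All CSV is UTF-8 with a header
# row and "." decimal separator.

#' Read a deconvoluted feature table
#'
#' The feature table is a CSV with columns `feature_id`, `rt_min`, `area`,
#' `replicate_id`, `spectrum_ref`; each row's `spectrum_ref` must name a
#' record (`Name:` field) in the companion MSP file holding the
#' deconvoluted spectra.
#'
#' @param path path to the CSV.
#' @param msp_path path to the companion MSP file with one record per
#'   referenced spectrum.
#' @return list of [ms_feature()].
#' @export
read_feature_table <- function(path, msp_path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("feature_id", "rt_min", "area", "replicate_id", "spectrum_ref")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(list())
  if (any(!is.finite(tab$area) | tab$area <= 0)) {
    stop("feature table: all areas must be positive")
  }
  if (any(!is.finite(tab$rt_min) | tab$rt_min <= 0)) {
    stop("feature table: all retention times must be positive")
  }
  specs <- read_msp(msp_path)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  dangling <- setdiff(tab$spectrum_ref, names(specs))
  if (length(dangling) > 0L) {
    stop("spectrum_ref not found in MSP: ", paste(dangling, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    ms_feature(
      feature_id = as.character(tab$feature_id[i]),
      rt = tab$rt_min[i],
      area = tab$area[i],
      spectrum = specs[[tab$spectrum_ref[i]]]$spectrum,
      replicate_id = as.character(tab$replicate_id[i])
    )
  })
}

#' Write a feature table (and its companion spectra MSP)
#'
#' @param features list of [ms_feature()].
#' @param path output CSV path.
#' @param msp_path output MSP path for the spectra.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, msp_path) {
  tab <- data.frame(
    feature_id = vapply(features, `[[`, character(1), "feature_id"),
    rt_min = vapply(features, `[[`, numeric(1), "rt"),
    area = vapply(features, `[[`, numeric(1), "area"),
    replicate_id = vapply(features, `[[`, character(1), "replicate_id"),
    stringsAsFactors = FALSE
  )
  tab$spectrum_ref <- paste0(tab$feature_id, "@", tab$replicate_id)
  utils::write.csv(tab, path, row.names = FALSE)
  recs <- lapply(seq_along(features), function(i) {
    library_record(name = tab$spectrum_ref[i], spectrum = features[[i]]$spectrum)
  })
  write_msp(recs, msp_path)
  invisible(path)
}

#' Read an n-alkane ladder file
#'
#' Two-column CSV (`carbon_number`, `rt_min`) mapping each injected
#' n-alkane to its retention time; consumed by [compute_ri()].
#'
#' @param path CSV path.
#' @return an [alkane_ladder()].
#' @export
read_alkane_ladder <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("carbon_number", "rt_min") %in% names(tab))) {
    stop("ladder file must have columns carbon_number, rt_min")
  }
  alkane_ladder(tab$carbon_number, tab$rt_min)
}

#' Read a compound annotation table
#'
#' CSV keyed by CAS number carrying Union-list membership with specific
#' migration limits (`sml_mg_kg`; empty when the substance is authorized
#' without a listed SML) and/or Cramer classes (`cramer_class`, one of
#' `I`, `II`, `III`).
#'
#' @param path CSV path with columns `cas` and any of `compound`,
#'   `ias`, `sml_mg_kg`, `cramer_class`.
#' @return data.frame keyed by `cas`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"cas" %in% names(tab)) stop("annotation table must have a 'cas' column")
  if ("sml_mg_kg" %in% names(tab)) {
    # "-" means authorized with no listed SML; keep the distinction
    tab$sml_no_limit <- tab$sml_mg_kg == "-"
    tab$sml_mg_kg <- suppressWarnings(as.numeric(tab$sml_mg_kg))
  }
  if ("ias" %in% names(tab)) tab$ias <- as.logical(tab$ias)
  if ("cramer_class" %in% names(tab)) {
    bad <- !tab$cramer_class %in% c("I", "II", "III", "", NA)
    if (any(bad)) stop("invalid Cramer class: ",
                       paste(unique(tab$cramer_class[bad]), collapse = ", "))
    tab$cramer_class[tab$cramer_class == ""] <- NA_character_
  }
  tab
}

#' Read internal-standard definitions
#'
#' CSV with columns `name`, `cas`, `spiked_conc_ng_ml`, `formula` plus one
#' `area_<replicate>` column per injection.
#'
#' @param path CSV path.
#' @return data.frame, one row per internal standard, with an `areas`
#'   list-column of per-replicate measured areas.
#' @export
read_internal_standards <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "spiked_conc_ng_ml")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop("internal-standard table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(tab$spiked_conc_ng_ml <= 0)) stop("spiked concentrations must be positive")
  area_cols <- grep("^area_", names(tab), value = TRUE)
  tab$areas <- lapply(seq_len(nrow(tab)), function(i) {
    as.numeric(tab[i, area_cols])
  })
  tab
}
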