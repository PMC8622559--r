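# Centroided EI spectra and the containers built on them.

#' Construct a centroided EI spectrum
#'
#' @param mz numeric vector of m/z values (Th, > 0). Peaks are re-ordered
#'   to strictly ascending m/z; exact duplicates are summed.
#' @param intensity numeric vector of intensities (>= 0), same length.
#' @return a `data.frame` of class `ei_spectrum` with columns `mz`,
#'   `intensity`.
#' @export
ei_spectrum <- function(mz, intensity) {
  if (length(mz) == 0L) stop("spectrum must contain at least one peak")
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("all m/z must be finite and positive")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("all intensities must be finite and non-negative")
  }
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  } else {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  structure(data.frame(mz = mz, intensity = intensity),
            class = c("ei_spectrum", "data.frame"))
}

is_spectrum <- function(x) inherits(x, "ei_spectrum")

base_peak_intensity <- function(spec) max(spec$intensity)

#' Construct a spectral library record
#'
#' One reference compound as stored in an MSP library: name, optional CAS,
#' molecular formula (optional — records without a formula cannot be scored
#' by high-resolution filtering), EI spectrum and optional library retention
#' index.
#'
#' @param name compound name.
#' @param spectrum an [ei_spectrum()].
#' @param formula an [elemental_formula()], formula string, or `NULL`.
#' @param cas CAS registry number string or `NA`.
#' @param library_ri library retention index (dimensionless, > 0) or `NA`.
#' @param source_tag free-text tag of the originating library/mass list.
#' @return object of class `library_record`.
#' @export
library_record <- function(name, spectrum, formula = NULL, cas = NA_character_,
                           library_ri = NA_real_, source_tag = NA_character_) {
  stopifnot(is.character(name), nzchar(name), is_spectrum(spectrum))
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!is.null(formula)) stopifnot(inherits(formula, "elemental_formula"))
  library_ri <- as.numeric(library_ri)
  if (!is.na(library_ri) && library_ri <= 0) stop("library_ri must be positive")
  structure(
    list(name = name, cas = as.character(cas), formula = formula,
         spectrum = spectrum, library_ri = library_ri,
         source_tag = as.character(source_tag)),
    class = "library_record"
  )
}

#' @export
print.library_record <- function(x, ...) {
  cat(sprintf("<library_record> %s [%s] %s, %d peaks, RI %s\n",
              x$name, x$cas,
              if (is.null(x$formula)) "(no formula)" else format(x$formula),
              nrow(x$spectrum),
              if (is.na(x$library_ri)) "-" else format(x$library_ri)))
  invisible(x)
}

#' Construct a deconvoluted chromatographic feature
#'
#' One deconvoluted GC feature from a single injection: retention time,
#' integrated peak area and its centroided EI spectrum.
#'
#' @param feature_id identifier string.
#' @param rt retention time in minutes (> 0).
#' @param area integrated peak area (> 0, arbitrary units).
#' @param spectrum an [ei_spectrum()].
#' @param replicate_id identifier of the injection/replicate.
#' @return object of class `ms_feature`.
#' @export
ms_feature <- function(feature_id, rt, area, spectrum, replicate_id = "R1") {
  stopifnot(is.character(feature_id), nzchar(feature_id))
  if (!is.finite(rt) || rt <= 0) stop("rt must be positive (minutes)")
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  stopifnot(is_spectrum(spectrum))
  structure(
    list(feature_id = feature_id, rt = rt, area = area,
         spectrum = spectrum, replicate_id = as.character(replicate_id)),
    class = "ms_feature"
  )
}

#' @export
print.ms_feature <- function(x, ...) {
  cat(sprintf("<ms_feature> %s (rep %s): rt %.3f min, area %.3g, %d peaks\n",
              x$feature_id, x$replicate_id, x$rt, x$area, nrow(x$spectrum)))
  invisible(x)
}
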