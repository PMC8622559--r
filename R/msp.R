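# Reader/writer for the NIST MSP text dialect used by EI spectral libraries.
#
# Accepted on input: "Num Peaks"/"NumPeaks" headers (case-insensitive),
# peak pairs separated by whitespace or ";". Output is always the NIST
# style: "Num Peaks: n" with one "mz intensity" pair per line.

#' Read an MSP spectral library
#'
#' @param path path to an MSP file. Records are separated by blank lines;
#'   each must declare its peak count (`Num Peaks:`). A record whose
#'   declared peak count disagrees with its peak lines is rejected with the
#'   record name in the error. A record without a `Formula:` field is
#'   loaded with `formula = NULL` (unusable for HRF scoring).
#' @return list of [library_record()].
#' @seealso [write_msp()]
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("MSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  # split into record blocks on blank lines
  blank <- !nzchar(trimws(lines))
  if (all(blank)) return(list())
  grp <- cumsum(blank)
  blocks <- split(lines[!blank], grp[!blank])
  lapply(unname(blocks), parse_msp_block)
}

parse_msp_block <- function(block) {
  fields <- list()
  peak_lines <- character(0)
  n_declared <- NA_integer_
  in_peaks <- FALSE
  for (ln in block) {
    if (!in_peaks && grepl("^[A-Za-z][A-Za-z _/]*:", ln)) {
      key <- tolower(gsub("[ _]", "", sub(":.*$", "", ln)))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (key == "numpeaks") {
        n_declared <- suppressWarnings(as.integer(val))
        in_peaks <- TRUE
      } else {
        fields[[key]] <- val
      }
    } else if (in_peaks) {
      peak_lines <- c(peak_lines, ln)
    } else {
      stop("malformed MSP line before Num Peaks: '", ln, "'")
    }
  }
  name <- fields[["name"]] %||% "(unnamed)"
  if (is.na(n_declared)) stop("record '", name, "': missing Num Peaks")
  toks <- unlist(strsplit(trimws(paste(peak_lines, collapse = " ")), "[;[:space:]]+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) %% 2L != 0L) {
    stop("record '", name, "': odd number of peak tokens")
  }
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals))) stop("record '", name, "': non-numeric peak value")
  n_found <- length(vals) %/% 2L
  if (n_found != n_declared) {
    stop("record '", name, "': declares ", n_declared,
         " peaks but has ", n_found)
  }
  if (n_found == 0L) stop("record '", name, "': empty spectrum")
  mzi <- matrix(vals, ncol = 2L, byrow = TRUE)
  formula <- fields[["formula"]]
  library_record(
    name = name,
    cas = fields[["cas"]] %||% fields[["casno"]] %||% NA_character_,
    formula = if (!is.null(formula) && nzchar(formula)) parse_formula(formula) else NULL,
    spectrum = ei_spectrum(mzi[, 1], mzi[, 2]),
    library_ri = as.numeric(fields[["ri"]] %||% fields[["retentionindex"]] %||% NA),
    source_tag = fields[["sourcetag"]] %||% fields[["source"]] %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write library records to an MSP file
#'
#' Emits the NIST text style; [read_msp()] of the output reproduces the
#' records (text fields exactly; m/z and intensity through a `%.6f`/`%g`
#' round trip).
#'
#' @param records list of [library_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(records, path) {
  stopifnot(is.list(records))
  out <- character(0)
  for (r in records) {
    stopifnot(inherits(r, "library_record"))
    hdr <- c(
      paste0("Name: ", r$name),
      if (!is.na(r$cas)) paste0("CAS: ", r$cas),
      if (!is.null(r$formula)) paste0("Formula: ", format(r$formula)),
      if (!is.na(r$library_ri)) paste0("RI: ", format(r$library_ri)),
      if (!is.na(r$source_tag)) paste0("SourceTag: ", r$source_tag),
      paste0("Num Peaks: ", nrow(r$spectrum))
    )
    pk <- sprintf("%.6f %g", r$spectrum$mz, r$spectrum$intensity)
    out <- c(out, hdr, pk, "")
  }
  writeLines(out, path)
  invisible(path)
}
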