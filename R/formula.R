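# Elemental-formula algebra and exact-mass arithmetic.
#
# All masses come from a static table of principal-isotope monoisotopic
# masses (CODATA/NIST values) embedded here, so that 2 ppm mass gating is
# hermetic and cannot drift with dependency versions.

# Principal (most abundant) isotope masses, Da.
.ISOTOPE_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.99491461956,
  F  = 18.99840322,
  Na = 22.9897692809,
  Mg = 23.9850417,
  Si = 27.9769265325,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Br = 78.9183371,
  I  = 126.904473
)

# Electron rest mass, Da. EI produces radical cations (M+.), whose
# theoretical m/z is the neutral monoisotopic mass minus one electron;
# at m/z 200 the electron mass is ~2.7 ppm, not negligible at a 2 ppm gate.
.ELECTRON_MASS <- 5.48579909e-4

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of per-element atom counts
#' plus a charge state, as used for molecular formulas of library records
#' and for fragment subformulas.
#'
#' @param counts named numeric vector of non-negative integer atom counts;
#'   names are element symbols known to the embedded isotope-mass table.
#' @param charge integer charge state (default 0; the radical-cation
#'   convention is applied at mass computation, not stored here).
#' @return an object of class `elemental_formula`.
#' @examples
#' elemental_formula(c(C = 15, H = 24, O = 1))
#' @export
elemental_formula <- function(counts, charge = 0L) {
  if (length(counts) == 0L || sum(counts) == 0) {
    stop("empty formula: at least one atom count must be positive")
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("formula counts must be named by element symbol")
  }
  unknown <- setdiff(names(counts), names(.ISOTOPE_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("atom counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  # canonical order: Hill system (C, H, then alphabetical)
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  structure(
    list(counts = as.integer(counts[ord]) |> stats::setNames(ord),
         charge = as.integer(charge)),
    class = "elemental_formula"
  )
}

#' Parse a molecular formula string
#'
#' Accepts the whitespace-separated style used in identification tables
#' (`"C15 H24 O"`) as well as the compact style (`"C15H24O"`). An element
#' symbol with no trailing count means one atom.
#'
#' @param text formula string.
#' @return an [elemental_formula()].
#' @examples
#' parse_formula("C15 H24 O")
#' parse_formula("C42H63O3P")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) stop("empty formula string")
  # tokens: one capital letter + optional lowercase + optional digits
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    covered <- unlist(mapply(function(st, len) st:(st + len - 1L),
                             as.integer(m), attr(m, "match.length"),
                             SIMPLIFY = FALSE))
    bad <- substr(s, setdiff(seq_len(nchar(s)), covered)[1], nchar(s))
    stop("malformed formula token near '", bad, "' in '", text, "'")
  }
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(.ISOTOPE_MASS)) {
      stop("unknown element symbol '", sym, "' in '", text, "'")
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  elemental_formula(counts)
}

#' Format an elemental formula as a string
#'
#' Inverse of [parse_formula()]: `parse_formula(format(f))` recovers `f`.
#'
#' @param x an `elemental_formula`.
#' @param compact if `TRUE` (default) emit `"C15H24O"`; otherwise the
#'   space-separated table style `"C15 H24 O"`.
#' @param ... unused.
#' @export
format.elemental_formula <- function(x, compact = TRUE, ...) {
  parts <- vapply(seq_along(x$counts), function(i) {
    n <- x$counts[[i]]
    paste0(names(x$counts)[i], if (n > 1L) n else "")
  }, character(1))
  paste(parts, collapse = if (compact) "" else " ")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format(x),
      if (x$charge != 0L) sprintf("(charge %+d)", x$charge), "\n")
  invisible(x)
}

#' @export
`==.elemental_formula` <- function(e1, e2) {
  identical(e1$counts, e2$counts) && identical(e1$charge, e2$charge)
}

n_atoms <- function(f) sum(f$counts)

#' Monoisotopic mass of a formula
#'
#' Sum of principal-isotope masses. With `as_radical_cation = TRUE` one
#' electron mass (5.48580e-4 Da) is subtracted, giving the theoretical m/z
#' of the EI radical cation; the same convention applies to fragment
#' subformulas treated as cations.
#'
#' @param f an [elemental_formula()] (or formula string, parsed on the fly).
#' @param as_radical_cation subtract one electron mass?
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("CH4"))
#' monoisotopic_mass("C15H24O", as_radical_cation = TRUE)
#' @export
monoisotopic_mass <- function(f, as_radical_cation = FALSE) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "elemental_formula"))
  m <- sum(.ISOTOPE_MASS[names(f$counts)] * f$counts)
  if (isTRUE(as_radical_cation)) m <- m - .ELECTRON_MASS
  unname(m)
}

#' Signed mass error in parts per million
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (must be > 0).
#' @return `1e6 * (observed - theoretical) / theoretical`, vectorised.
#' @examples
#' ppm_error(200.00000, 200.00040)  # -2 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}
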