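# Retention-index calibration against n-alkane ladders.
#
# The linear (van den Dool-Kratz) convention is used: under a
# temperature-programmed oven ramp, retention index interpolates linearly
# in retention time between bracketing n-alkanes, with the alkane of n
# carbons defining RI = 100 * n. RI is dimensionless; retention times are
# minutes throughout.

#' Construct an n-alkane ladder
#'
#' @param carbon_number integer carbon numbers of the injected n-alkanes
#'   (>= 2 entries).
#' @param rt retention times in minutes; must be strictly increasing with
#'   carbon number.
#' @return object of class `alkane_ladder`.
#' @export
alkane_ladder <- function(carbon_number, rt) {
  stopifnot(length(carbon_number) == length(rt))
  if (length(carbon_number) < 2L) {
    stop("an alkane ladder needs at least 2 anchors")
  }
  if (anyDuplicated(carbon_number)) stop("duplicate carbon numbers in ladder")
  o <- order(carbon_number)
  carbon_number <- as.integer(carbon_number[o])
  rt <- as.numeric(rt[o])
  if (any(diff(rt) <= 0)) {
    stop("ladder retention times must increase strictly with carbon number")
  }
  structure(data.frame(carbon_number = carbon_number, rt = rt),
            class = c("alkane_ladder", "data.frame"))
}

#' Merge two alkane ladders
#'
#' Anchors present in both ladders must agree in retention time (within
#' `rt_tol` minutes); the merged ladder keeps one entry per carbon number.
#'
#' @param a,b [alkane_ladder()] objects.
#' @param rt_tol agreement tolerance for shared anchors, minutes.
#' @return merged [alkane_ladder()].
#' @export
merge_ladders <- function(a, b, rt_tol = 1e-6) {
  stopifnot(inherits(a, "alkane_ladder"), inherits(b, "alkane_ladder"))
  shared <- intersect(a$carbon_number, b$carbon_number)
  for (n in shared) {
    if (abs(a$rt[a$carbon_number == n] - b$rt[b$carbon_number == n]) > rt_tol) {
      stop("ladders disagree at C", n)
    }
  }
  only_b <- b[!b$carbon_number %in% a$carbon_number, ]
  alkane_ladder(c(a$carbon_number, only_b$carbon_number),
                c(a$rt, only_b$rt))
}

#' Compute a retention index
#'
#' Van den Dool-Kratz linear interpolation between the bracketing alkane
#' anchors: for bracketing carbon numbers n < m,
#' `ri = 100*n + 100*(m - n)*(rt - rt_n)/(rt_m - rt_n)`. Retention times
#' outside the ladder are extrapolated linearly from the terminal anchor
#' pair and flagged.
#'
#' @param rt retention time in minutes.
#' @param ladder an [alkane_ladder()].
#' @return object of class `ri_value`: list with `ri` (dimensionless) and
#'   `extrapolated` (flag).
#' @export
compute_ri <- function(rt, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"), is.finite(rt))
  n <- nrow(ladder)
  i <- findInterval(rt, ladder$rt, rightmost.closed = FALSE)
  extrapolated <- i == 0L || i >= n
  i <- min(max(i, 1L), n - 1L)  # terminal pair for extrapolation
  # exact anchor hits are never "extrapolated"
  if (rt == ladder$rt[n]) extrapolated <- FALSE
  c1 <- ladder$carbon_number[i]; c2 <- ladder$carbon_number[i + 1L]
  t1 <- ladder$rt[i]; t2 <- ladder$rt[i + 1L]
  ri <- 100 * c1 + 100 * (c2 - c1) * (rt - t1) / (t2 - t1)
  structure(list(ri = ri, extrapolated = extrapolated), class = "ri_value")
}

#' @export
print.ri_value <- function(x, ...) {
  cat(sprintf("<ri_value> %.1f%s\n", x$ri,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Absolute retention-index difference versus a library value
#'
#' @param calculated an `ri_value` (from [compute_ri()]) or bare number.
#' @param library_ri library retention index, or `NA` when the library has
#'   none (the RI criterion is then vacuous and `NA` is returned).
#' @return `|calculated - library_ri|`, or `NA`.
#' @export
delta_ri <- function(calculated, library_ri) {
  ri <- if (inherits(calculated, "ri_value")) calculated$ri
        else as.numeric(calculated)
  if (is.na(library_ri)) return(NA_real_)
  abs(ri - library_ri)
}
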