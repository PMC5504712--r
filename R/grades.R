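# Occurrence grades: ordinal frequency symbols attached to pathophems.
# The five positive grades map to disjoint probability intervals; NOT is an
# exclusion marker, not an interval. The printed bounds leave gaps (e.g.
# nothing between 0.09 and 0.1); the mapping reproduces them verbatim.

.grade_table <- data.frame(
  symbol     = c("Lead", "+++", "++", "+", "(+)"),
  lower      = c(1.0, 0.50, 0.10, 0.01, 0.00),
  upper      = c(1.0, 0.99, 0.49, 0.09, 0.01),
  upper_open = c(FALSE, FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Occurrence grade symbols
#'
#' The six grade symbols in decreasing order of occurrence probability,
#' ending with the exclusion marker `NOT`.
#'
#' @return Character vector `c("Lead", "+++", "++", "+", "(+)", "NOT")`.
#' @export
grade_symbols <- function() c(.grade_table$symbol, "NOT")

#' Probability interval of an occurrence grade
#'
#' Maps a grade symbol to its occurrence-probability interval. `Lead` means a
#' finding is always present (probability 1); the remaining positive grades
#' cover decreasing frequency bands; `NOT` marks a finding that excludes the
#' disease prototype and carries no interval.
#'
#' @param symbol One of `"Lead"`, `"+++"`, `"++"`, `"+"`, `"(+)"`, `"NOT"`.
#' @return For positive grades, an object of class `grade_interval` with
#'   fields `lower`, `upper` and `upper_open`; for `"NOT"`, an exclusion
#'   marker of class `grade_exclusion`.
#' @examples
#' grade_interval("Lead")   # [1, 1]
#' grade_interval("+++")    # [0.5, 0.99]
#' grade_interval("NOT")    # exclusion marker
#' @export
grade_interval <- function(symbol) {
  if (identical(symbol, "NOT")) {
    return(structure(list(exclusion = TRUE), class = "grade_exclusion"))
  }
  i <- match(symbol, .grade_table$symbol)
  if (is.na(i)) {
    stop("invalid grade symbol: ", deparse(symbol), call. = FALSE)
  }
  structure(
    list(lower = .grade_table$lower[i], upper = .grade_table$upper[i],
         upper_open = .grade_table$upper_open[i]),
    class = "grade_interval"
  )
}

#' Scalar weight of an occurrence grade
#'
#' Scalarizes a positive grade to the midpoint of its probability interval,
#' used by the ranking score. Weights are strictly increasing along the
#' grade order `(+) < + < ++ < +++ < Lead`.
#'
#' @param symbol A positive grade symbol (`"NOT"` is an error: exclusion is
#'   handled separately, not weighted).
#' @return A number in `[0, 1]`.
#' @examples
#' grade_weight("Lead")  # 1
#' grade_weight("+++")   # 0.745
#' @export
grade_weight <- function(symbol) {
  if (identical(symbol, "NOT")) {
    stop("grade 'NOT' has no weight: it is an exclusion, not a frequency",
         call. = FALSE)
  }
  i <- match(symbol, .grade_table$symbol)
  if (is.na(i)) {
    stop("invalid grade symbol: ", deparse(symbol), call. = FALSE)
  }
  (.grade_table$lower[i] + .grade_table$upper[i]) / 2
}

#' @export
print.grade_interval <- function(x, ...) {
  cat(sprintf("[%g, %g%s\n", x$lower, x$upper, if (x$upper_open) ")" else "]"))
  invisible(x)
}

#' @export
print.grade_exclusion <- function(x, ...) {
  cat("exclusion (NOT)\n")
  invisible(x)
}

# Probability an explicit numeric occurrence value must fall into for the
# given grade; used when a KB stores both a symbol and a number.
.prob_in_grade <- function(p, symbol) {
  iv <- grade_interval(symbol)
  if (inherits(iv, "grade_exclusion")) return(FALSE)
  p >= iv$lower && (if (iv$upper_open) p < iv$upper else p <= iv$upper)
}
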