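# The coded pathophem expression language.
#
# Grammar (whitespace insignificant):
#   expr    := clause (';' clause)*          -- top-level conjunction (SEQ)
#   clause  := conj ('|' conj)*              -- OR
#   conj    := factor ('&' factor)*          -- AND
#   factor  := '(' clause ')' | atom
#   atom    := CODE [FLAG] '|' [':' constraint]
#   constraint := NUM '..' NUM [UNIT] | TOKEN [UNIT]
#
# A '|' immediately terminating a CODE (plus optional one-letter flag) is the
# atom terminator; any other '|' is the OR operator. Evaluation is Kleene
# three-valued: facts are TRUE, FALSE, a number (with optional unit) or
# absent (not available).

.syntax_error <- function(pos, expected, found) {
  stop(structure(
    class = c("dsl_syntax_error", "error", "condition"),
    list(message = sprintf("syntax error at position %d: expected %s, found %s",
                           pos, expected, found),
         call = NULL, pos = pos, expected = expected)))
}

#' Expression-node constructors
#'
#' Build rule ASTs programmatically. `expr_atom()` is a coded term reference
#' with an optional one-letter flag and an optional attribute constraint;
#' `expr_and()`, `expr_or()` and `expr_seq()` are the connectives (`expr_seq`
#' is the top-level `';'` conjunction and may only appear as the root).
#'
#' @param code Term code (optional letter + digits + optional flag letter).
#' @param flag Optional single-letter flag, kept opaque (e.g. `"T"`).
#' @param constraint Optional [range_constraint()] or [value_constraint()].
#' @param ... Two or more child expression nodes.
#' @return An object of class `expr_node`.
#' @export
expr_atom <- function(code, flag = NULL, constraint = NULL) {
  if (!grepl(.term_code_pattern, code)) {
    stop("invalid atom code: ", deparse(code), call. = FALSE)
  }
  structure(list(variant = "ATOM", code = code, flag = flag,
                 constraint = constraint), class = "expr_node")
}

.expr_nary <- function(variant, children) {
  children <- lapply(children, function(x) {
    stopifnot(inherits(x, "expr_node")); x
  })
  structure(list(variant = variant, children = children), class = "expr_node")
}

#' @rdname expr_atom
#' @export
expr_and <- function(...) .expr_nary("AND", list(...))

#' @rdname expr_atom
#' @export
expr_or <- function(...) .expr_nary("OR", list(...))

#' @rdname expr_atom
#' @export
expr_seq <- function(...) .expr_nary("SEQ", list(...))

#' Attribute constraints on rule atoms
#'
#' `range_constraint(lo, hi)` is satisfied by a numeric fact `v` with
#' `lo <= v < hi` (closed-lower, open-upper); `value_constraint(value)` by an
#' equal fact. Units are compared when both the fact and the constraint carry
#' one.
#'
#' @param lo,hi Numeric bounds with `lo < hi`.
#' @param value A number or category string.
#' @param unit Optional unit string (e.g. `"%"`).
#' @export
range_constraint <- function(lo, hi, unit = NULL) {
  stopifnot(is.numeric(lo), is.numeric(hi))
  if (!(lo < hi)) stop("range requires lo < hi", call. = FALSE)
  list(type = "range", lo = as.numeric(lo), hi = as.numeric(hi), unit = unit)
}

#' @rdname range_constraint
#' @export
value_constraint <- function(value, unit = NULL) {
  if (is.numeric(value)) value <- as.numeric(value)
  list(type = "value", value = value, unit = unit)
}

# --- lexer ------------------------------------------------------------------

.lex_rule <- function(text) {
  tokens <- list()
  n <- nchar(text)
  i <- 1L
  push <- function(type, pos, ...) {
    tokens[[length(tokens) + 1L]] <<- c(list(type = type, pos = pos),
                                        list(...))
  }
  re_atom <- "^([A-Z]?[0-9]+[A-Z]?)[ \t]*([A-Z](?![A-Za-z0-9]))?[ \t]*\\|"
  re_range <- "^[ \t]*([0-9]+(?:\\.[0-9]+)?)[ \t]*\\.\\.[ \t]*([0-9]+(?:\\.[0-9]+)?)[ \t]*(%|[A-Za-z][A-Za-z/]*)?"
  re_value <- "^[ \t]*([A-Za-z0-9_.+-]+?)[ \t]*(%)?(?=[ \t]|$|[;&|()])"
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws)) { i <- i + nchar(ws); next }
    rest <- substr(text, i, n)
    ch <- substr(rest, 1, 1)
    m <- regexec(re_atom, rest, perl = TRUE)[[1]]
    if (m[1] != -1) {
      parts <- regmatches(rest, regexec(re_atom, rest, perl = TRUE))[[1]]
      consumed <- nchar(parts[1])
      code <- parts[2]
      flag <- if (nchar(parts[3])) parts[3] else NULL
      pos <- i
      i <- i + consumed
      # optional constraint
      constraint <- NULL
      rest2 <- substr(text, i, n)
      colon <- regmatches(rest2, regexpr("^\\s*:", rest2))
      if (length(colon)) {
        i <- i + nchar(colon)
        rest3 <- substr(text, i, n)
        mr <- regmatches(rest3, regexec(re_range, rest3, perl = TRUE))[[1]]
        if (length(mr) && nchar(mr[1])) {
          lo <- as.numeric(mr[2]); hi <- as.numeric(mr[3])
          unit <- if (nchar(mr[4])) mr[4] else NULL
          if (!(lo < hi)) .syntax_error(i, "range with lo < hi",
                                        sprintf("%g..%g", lo, hi))
          constraint <- range_constraint(lo, hi, unit)
          i <- i + nchar(mr[1])
        } else {
          mv <- regmatches(rest3, regexec(re_value, rest3, perl = TRUE))[[1]]
          if (!length(mv) || !nchar(mv[1])) {
            .syntax_error(i, "a constraint (range or value)",
                          if (nchar(rest3)) substr(rest3, 1, 10) else "end of input")
          }
          val <- mv[2]
          num <- suppressWarnings(as.numeric(val))
          unit <- if (nchar(mv[3])) mv[3] else NULL
          constraint <- value_constraint(if (!is.na(num)) num else val, unit)
          i <- i + nchar(mv[1])
        }
      }
      push("ATOM", pos, code = code, flag = flag, constraint = constraint)
      next
    }
    if (ch == "&") { push("AND", i); i <- i + 1L; next }
    if (ch == "|") { push("OR", i); i <- i + 1L; next }
    if (ch == ";") { push("SEMI", i); i <- i + 1L; next }
    if (ch == "(") { push("LPAREN", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", i); i <- i + 1L; next }
    .syntax_error(i, "an atom, operator or parenthesis", deparse(ch))
  }
  push("EOF", n + 1L)
  tokens
}

# --- parser -----------------------------------------------------------------

#' Parse a coded pathophem expression
#'
#' Parses the coded Boolean rule language attached to pathosoms, e.g. the
#' myelodysplasia rule
#' `"M3094|; (O812| & 10209|: 5..20%) | (10221 T| &10209 T|: 2..20%)"`.
#' `';'` is the top-level conjunction, `'&'` binds tighter than the OR
#' `'|'`, parentheses group, and an atom is a term code (plus optional
#' one-letter flag) terminated by `'|'` with an optional `':'` constraint
#' (a half-open percentage/unit range `lo..hi` or a plain value).
#'
#' @param text Non-empty expression string.
#' @return The AST root, an `expr_node`.
#' @seealso [eval_rule()], [serialize_rule()]
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) {
    stop("empty expression", call. = FALSE)
  }
  toks <- .lex_rule(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  peek <- function() toks[[st$i]]
  advance <- function() { t <- toks[[st$i]]; st$i <- st$i + 1L; t }
  tok_desc <- function(t) {
    switch(t$type, EOF = "end of input", ATOM = paste0("atom ", t$code),
           t$type)
  }

  parse_factor <- function() {
    t <- peek()
    if (t$type == "ATOM") {
      advance()
      return(expr_atom(t$code, t$flag, t$constraint))
    }
    if (t$type == "LPAREN") {
      advance()
      node <- parse_clause()
      t2 <- peek()
      if (t2$type != "RPAREN") .syntax_error(t2$pos, "')'", tok_desc(t2))
      advance()
      return(node)
    }
    .syntax_error(t$pos, "an atom or '('", tok_desc(t))
  }
  parse_conj <- function() {
    children <- list(parse_factor())
    while (peek()$type == "AND") {
      advance()
      children[[length(children) + 1L]] <- parse_factor()
    }
    if (length(children) == 1L) children[[1L]] else .expr_nary("AND", children)
  }
  parse_clause <- function() {
    children <- list(parse_conj())
    while (peek()$type == "OR") {
      advance()
      children[[length(children) + 1L]] <- parse_conj()
    }
    if (length(children) == 1L) children[[1L]] else .expr_nary("OR", children)
  }

  clauses <- list(parse_clause())
  while (peek()$type == "SEMI") {
    advance()
    clauses[[length(clauses) + 1L]] <- parse_clause()
  }
  t <- peek()
  if (t$type != "EOF") .syntax_error(t$pos, "';', an operator or end of input",
                                     tok_desc(t))
  if (length(clauses) == 1L) clauses[[1L]] else .expr_nary("SEQ", clauses)
}

# --- evaluator --------------------------------------------------------------

.fact_parts <- function(f) {
  if (is.list(f)) list(value = f$value, unit = f$unit %||% NULL)
  else list(value = f, unit = NULL)
}

.atom_key <- function(node) {
  if (is.null(node$flag)) node$code else paste(node$code, node$flag)
}

.eval_atom <- function(node, facts) {
  f <- facts[[.atom_key(node)]]
  if (is.null(f)) return(NA)
  fp <- .fact_parts(f)
  v <- fp$value
  if (is.null(node$constraint)) {
    if (is.logical(v)) return(v)
    return(TRUE)  # a recorded value means the finding is present
  }
  con <- node$constraint
  if (is.logical(v)) {
    # presence known but magnitude not: cannot decide the constraint
    return(if (isFALSE(v)) FALSE else NA)
  }
  if (!is.null(fp$unit) && !is.null(con$unit) &&
      !identical(fp$unit, con$unit)) {
    stop(sprintf("unit mismatch for %s: fact in '%s', constraint in '%s'",
                 .atom_key(node), fp$unit, con$unit), call. = FALSE)
  }
  if (con$type == "range") {
    if (!is.numeric(v)) {
      stop("range constraint on ", .atom_key(node),
           " tested against a non-numeric fact", call. = FALSE)
    }
    return(v >= con$lo && v < con$hi)
  }
  if (is.numeric(con$value) && is.numeric(v)) return(v == con$value)
  identical(as.character(v), as.character(con$value))
}

#' Evaluate a rule against a fact set
#'
#' Kleene three-valued evaluation: each atom is TRUE, FALSE or NA (not
#' available); in a conjunction FALSE dominates and NA beats TRUE; in a
#' disjunction TRUE dominates and NA beats FALSE. The top-level `';'`
#' sequence behaves as a conjunction. An atom with a range constraint is
#' TRUE iff the fact's numeric value `v` satisfies `lo <= v < hi`, FALSE if
#' a value exists outside the range, and NA if the code is absent or only
#' known to be present.
#'
#' @param rule An `expr_node` (from [parse_rule()] or the constructors) or
#'   an expression string.
#' @param facts Named list mapping atom keys (the code, or `"code F"` for a
#'   flagged atom) to `TRUE`/`FALSE`, a number, or `list(value =, unit =)`.
#'   Absent keys mean not-available.
#' @return `TRUE`, `FALSE` or `NA`.
#' @examples
#' r <- parse_rule("M3094|; (O812| & 10209|: 5..20%)")
#' eval_rule(r, list(M3094 = TRUE, O812 = TRUE,
#'                   `10209` = list(value = 12, unit = "%")))
#' @export
eval_rule <- function(rule, facts = list()) {
  if (is.character(rule)) rule <- parse_rule(rule)
  stopifnot(inherits(rule, "expr_node"))
  rec <- function(node) {
    switch(node$variant,
      ATOM = .eval_atom(node, facts),
      AND  = ,
      SEQ  = all(vapply(node$children, rec, logical(1))),
      OR   = any(vapply(node$children, rec, logical(1))),
      stop("unknown expression variant: ", node$variant))
  }
  rec(rule)
}

# --- serializer -------------------------------------------------------------

.fmt_num <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
  # widen only when 15 significant digits do not reproduce the double
  if (as.numeric(s) != x) {
    s <- format(x, scientific = FALSE, trim = TRUE, digits = 17)
  }
  s
}

.serialize_constraint <- function(con) {
  if (is.null(con)) return("")
  if (con$type == "range") {
    paste0(": ", .fmt_num(con$lo), "..", .fmt_num(con$hi), con$unit %||% "")
  } else {
    v <- if (is.numeric(con$value)) .fmt_num(con$value) else con$value
    paste0(": ", v, con$unit %||% "")
  }
}

#' Serialize a rule AST to the coded expression language
#'
#' Produces a canonical string (single spaces around operators, minimal
#' parentheses) such that `parse_rule(serialize_rule(ast))` is structurally
#' identical to `ast`. A `SEQ` node is only legal at the root and every
#' connective must have at least two children.
#'
#' @param ast An `expr_node`.
#' @return The expression string.
#' @export
serialize_rule <- function(ast) {
  stopifnot(inherits(ast, "expr_node"))
  prec <- function(node) switch(node$variant,
                                ATOM = 3L, AND = 2L, OR = 1L, SEQ = 0L)
  rec <- function(node, top) {
    if (node$variant == "ATOM") {
      return(paste0(node$code,
                    if (!is.null(node$flag)) paste0(" ", node$flag) else "",
                    "|", .serialize_constraint(node$constraint)))
    }
    if (node$variant == "SEQ" && !top) {
      stop("SEQ is only legal at the expression root", call. = FALSE)
    }
    if (length(node$children) < 2L) {
      stop(node$variant, " node requires at least 2 children", call. = FALSE)
    }
    sep <- switch(node$variant, SEQ = "; ", AND = " & ", OR = " | ")
    parts <- vapply(node$children, function(ch) {
      s <- rec(ch, top = FALSE)
      # parenthesize children binding no tighter than the parent so the
      # serialized form re-parses to the identical tree (no flattening)
      if (ch$variant != "ATOM" && prec(ch) <= prec(node)) paste0("(", s, ")")
      else s
    }, character(1))
    paste(parts, collapse = sep)
  }
  rec(ast, top = TRUE)
}

#' @export
print.expr_node <- function(x, ...) {
  cat("<rule> ", serialize_rule(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.expr_node <- function(x, ...) serialize_rule(x)
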