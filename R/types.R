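# Core domain types: thesaurus cross-references, class codes, atomistic
# terms, attributes, pathophems, pathosoms and the knowledge base container.

`%||%` <- function(a, b) if (is.null(a)) b else a

.thesauri <- c("ICD-10-GM", "ICD-O", "ORPHANET", "OPS", "LOINC", "OMIM",
               "TA", "CAS", "EC", "HGNC", "ATC")
.languages <- c("de", "en", "la")
.term_code_pattern <- "^[A-Z]?[0-9]+[A-Z]?$"
.attr_kinds <- c("cardinal", "ordinal", "numeric")

.class_cache <- new.env(parent = emptyenv())

#' Packaged class taxonomy
#'
#' The classification table every term and pathophem is class-divided
#' against: a four-digit code plus a (class, subclass, subclass2) label path
#' covering descriptions, symptoms (anamnesis, vital, physical, laboratory,
#' imaging, pathology, genetics), disease characteristics (epidemiology,
#' etiology, course) and therapy.
#'
#' @return A data.frame with columns `code` (integer), `class`, `subclass`,
#'   `subclass2` (character; empty string when absent).
#' @export
class_table <- function() {
  if (is.null(.class_cache$tab)) {
    path <- system.file("extdata", "class_table.tsv", package = "pathosom")
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character", quote = "",
                             fill = TRUE, encoding = "UTF-8")
    tab$code <- as.integer(tab$code)
    tab$subclass2[is.na(tab$subclass2)] <- ""
    .class_cache$tab <- tab
  }
  .class_cache$tab
}

#' Class code lookup
#'
#' @param code Integer class code (e.g. 5500 for laboratory findings).
#' @return A list with `code` and `class_path` (character triple), or `NULL`
#'   if the code is not in the packaged table.
#' @export
class_info <- function(code) {
  tab <- class_table()
  i <- match(as.integer(code), tab$code)
  if (is.na(i)) return(NULL)
  list(code = tab$code[i],
       class_path = c(tab$class[i], tab$subclass[i], tab$subclass2[i]))
}

#' Thesaurus cross-reference
#'
#' A pointer from an internal term or pathosom to its code in one of the
#' harmonized external thesauri (ICD-10-GM, ICD-O, ORPHANET, OPS, LOINC,
#' OMIM, TA, CAS, EC, HGNC, ATC). Codes are opaque strings in the target
#' thesaurus's own syntax.
#'
#' @param thesaurus One of the eleven thesaurus acronyms.
#' @param code Non-empty code string, e.g. `"D46.2"` or `"9983/3"`.
#' @export
thesaurus_ref <- function(thesaurus, code) {
  if (!is.character(thesaurus) || length(thesaurus) != 1 ||
      !(thesaurus %in% .thesauri)) {
    stop("unknown thesaurus: ", deparse(thesaurus), "; must be one of ",
         paste(.thesauri, collapse = ", "), call. = FALSE)
  }
  if (!is.character(code) || length(code) != 1 || !nzchar(code)) {
    stop("thesaurus code must be a non-empty string", call. = FALSE)
  }
  structure(list(thesaurus = thesaurus, code = code), class = "thesaurus_ref")
}

#' Attribute of a term or pathophem
#'
#' Attributes qualify a stem-word concept (time, intensity, color, site,
#' age, ...). They are cardinal (an unordered category), ordinal (a level on
#' a declared scale) or numeric (a value or half-open interval `[lo, hi)`
#' with an optional unit).
#'
#' @param name Attribute name, e.g. `"intensity"`, `"site"`, `"age"`.
#' @param value A category string (cardinal), a level present in `scale`
#'   (ordinal), a single number, or a length-2 numeric `c(lo, hi)` interval
#'   with `lo < hi` (numeric).
#' @param kind Optional; inferred from `value`/`scale` when omitted.
#' @param unit Optional unit string for numeric attributes (e.g. `"years"`,
#'   `"%"`).
#' @param scale Ordered character vector of levels for ordinal attributes.
#' @export
attribute <- function(name, value, kind = NULL, unit = NULL, scale = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (is.null(kind)) {
    kind <- if (!is.null(scale)) "ordinal"
            else if (is.numeric(value)) "numeric"
            else "cardinal"
  }
  if (!(kind %in% .attr_kinds)) {
    stop("attribute kind must be one of ",
         paste(.attr_kinds, collapse = ", "), call. = FALSE)
  }
  if (kind == "numeric") {
    if (!is.numeric(value) || !(length(value) %in% 1:2)) {
      stop("numeric attribute value must be a number or a c(lo, hi) interval",
           call. = FALSE)
    }
    if (length(value) == 2 && !(value[1] < value[2])) {
      stop("numeric interval requires lo < hi", call. = FALSE)
    }
  } else if (kind == "ordinal") {
    if (is.null(scale) || !is.character(scale) || length(scale) < 2) {
      stop("ordinal attribute requires a declared scale of >= 2 levels",
           call. = FALSE)
    }
    if (!(value %in% scale)) {
      stop("ordinal level ", deparse(value), " not on the declared scale",
           call. = FALSE)
    }
  } else {
    if (!is.character(value) || length(value) != 1) {
      stop("cardinal attribute value must be a single category string",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, name = name, value = value,
                 unit = unit, scale = scale),
            class = "kb_attribute")
}

#' Atomistic term
#'
#' A stem-word medical concept with a singular internal code, multilingual
#' labels (German, English, Latin), a class code, and cross-references into
#' external thesauri.
#'
#' @param term_code Code matching optional uppercase letter + digits +
#'   optional uppercase flag letter (e.g. `"M3094"`, `"O812"`, `"10209"`,
#'   `"10787Z"`).
#' @param labels Named character vector; names are language tags (`de`,
#'   `en`, `la`) and may repeat, e.g.
#'   `c(en = "renal cyst", en = "renal cysts", de = "Nierenzyste")`.
#' @param class_code Integer class code (see [class_table()]).
#' @param xrefs List of [thesaurus_ref()] objects.
#' @export
atomistic_term <- function(term_code, labels, class_code, xrefs = list()) {
  if (!grepl(.term_code_pattern, term_code)) {
    stop("term code ", deparse(term_code),
         " does not match the code pattern (optional letter + digits + ",
         "optional flag letter)", call. = FALSE)
  }
  if (length(labels) < 1) stop("a term needs at least one label", call. = FALSE)
  if (is.character(labels)) {
    langs <- names(labels) %||% rep("en", length(labels))
    labels <- data.frame(language = unname(langs), surface = unname(labels),
                         stringsAsFactors = FALSE)
  }
  if (!all(labels$language %in% .languages)) {
    stop("label languages must be one of ",
         paste(.languages, collapse = ", "), call. = FALSE)
  }
  for (x in xrefs) stopifnot(inherits(x, "thesaurus_ref"))
  structure(list(term_code = term_code, labels = labels,
                 class_code = as.integer(class_code), xrefs = xrefs),
            class = "atomistic_term")
}

#' Pathophem: one attributed finding inside a disease prototype
#'
#' An object sentence after atomization: a coded stem-word subject, up to
#' three attributes, and an occurrence grade (or the `NOT` exclusion flag).
#' An explicit occurrence probability may be stored alongside the grade; when
#' both are present the numeric value wins for ranking weight. Explicit
#' probabilities falling in the gaps between the printed grade intervals
#' (e.g. 0.095) are rejected.
#'
#' @param subject Term code of the finding.
#' @param grade Grade symbol, see [grade_symbols()].
#' @param attributes List of at most three [attribute()] objects.
#' @param prob Optional explicit occurrence probability in `[0, 1]`.
#' @param class_code Optional class code; defaults to the subject term's
#'   class when the pathophem lives in a knowledge base.
#' @export
pathophem <- function(subject, grade = "+", attributes = list(),
                      prob = NULL, class_code = NULL) {
  if (!grepl(.term_code_pattern, subject)) {
    stop("pathophem subject ", deparse(subject), " is not a valid term code",
         call. = FALSE)
  }
  if (!(grade %in% grade_symbols())) {
    stop("invalid grade symbol: ", deparse(grade), call. = FALSE)
  }
  if (length(attributes) > 3) {
    stop("a pathophem carries at most 3 attributes", call. = FALSE)
  }
  for (a in attributes) stopifnot(inherits(a, "kb_attribute"))
  if (!is.null(prob)) {
    stopifnot(is.numeric(prob), length(prob) == 1, prob >= 0, prob <= 1)
    if (grade == "NOT") {
      stop("an excluding (NOT) pathophem carries no occurrence probability",
           call. = FALSE)
    }
    in_any <- any(vapply(.grade_table$symbol, function(s)
      .prob_in_grade(prob, s), logical(1)))
    if (!in_any) {
      stop("occurrence probability ", prob,
           " falls in a gap between grade intervals", call. = FALSE)
    }
  }
  structure(list(subject = subject, attributes = attributes, grade = grade,
                 prob = prob, class_code = if (is.null(class_code)) NULL
                                           else as.integer(class_code)),
            class = "pathophem")
}

# ranking weight of a pathophem: explicit probability wins over the grade
.ph_weight <- function(ph) ph$prob %||% grade_weight(ph$grade)

#' Pathosom: a prototypic disease vector
#'
#' A disease prototype defined as a vector of pathophems, optionally guarded
#' by a coded Boolean rule (see [parse_rule()]), and embedded in a subset
#' tree (`parent`/`children`, i.e. is-element-of / has-element) with
#' optional variants.
#'
#' @param pathosom_id Identifier following the term-code pattern (e.g.
#'   `"M3501"`).
#' @param name Human-readable disease name.
#' @param pathophems List of [pathophem()] objects.
#' @param rule Optional coded Boolean expression string; must parse.
#' @param parent Optional parent pathosom id.
#' @param children,variants Character vectors of pathosom ids.
#' @param xrefs List of [thesaurus_ref()] objects.
#' @export
pathosom <- function(pathosom_id, name, pathophems = list(), rule = NULL,
                     parent = NULL, children = character(),
                     variants = character(), xrefs = list()) {
  if (!grepl(.term_code_pattern, pathosom_id)) {
    stop("pathosom id ", deparse(pathosom_id), " is not a valid code",
         call. = FALSE)
  }
  stopifnot(is.character(name), length(name) == 1)
  pathophems <- unname(pathophems)
  for (p in pathophems) stopifnot(inherits(p, "pathophem"))
  if (!is.null(rule)) parse_rule(rule)  # fail fast on syntax errors
  for (x in xrefs) stopifnot(inherits(x, "thesaurus_ref"))
  structure(list(pathosom_id = pathosom_id, name = name,
                 pathophems = pathophems, rule = rule, parent = parent,
                 children = as.character(children),
                 variants = as.character(variants), xrefs = xrefs),
            class = "pathosom")
}

#' Knowledge base of terms, pathosoms and semantic-network edges
#'
#' The container tying the three components together: a lexicon of atomistic
#' terms, the pool of pathosoms, and the typed semantic network. Pathosom
#' tree links (`parent`, `children`, `variants`) are mirrored into the
#' network as `is-element-of` / `has-element` / `has-variant` edges.
#'
#' @param lexicon List of [atomistic_term()] objects.
#' @param pathosoms List of [pathosom()] objects.
#' @param edges Optional data.frame with columns `source`, `edge_type`,
#'   `target` (see [semantic_net()]).
#' @return An object of class `knowledge_base` with fields `lexicon`
#'   (named list), `pathosoms` (named list) and `net` ([semantic_net()]).
#' @export
knowledge_base <- function(lexicon = list(), pathosoms = list(),
                           edges = NULL) {
  for (t in lexicon) stopifnot(inherits(t, "atomistic_term"))
  for (p in pathosoms) stopifnot(inherits(p, "pathosom"))
  tcodes <- vapply(lexicon, `[[`, character(1), "term_code")
  pcodes <- vapply(pathosoms, `[[`, character(1), "pathosom_id")
  if (anyDuplicated(tcodes)) {
    stop("duplicate term codes: ",
         paste(unique(tcodes[duplicated(tcodes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pcodes)) {
    stop("duplicate pathosom ids: ",
         paste(unique(pcodes[duplicated(pcodes)]), collapse = ", "),
         call. = FALSE)
  }
  lexicon <- stats::setNames(lexicon, tcodes)[order(tcodes)]
  pathosoms <- stats::setNames(pathosoms, pcodes)[order(pcodes)]

  tree <- .tree_edges(pathosoms)
  if (is.null(edges)) edges <- .empty_edges()
  edges <- rbind(edges[, c("source", "edge_type", "target")], tree)
  edges <- unique(edges)
  nodes <- sort(unique(c(tcodes, pcodes, edges$source, edges$target)))
  net <- semantic_net(edges, nodes)
  structure(list(lexicon = lexicon, pathosoms = pathosoms, net = net),
            class = "knowledge_base")
}

.empty_edges <- function() {
  data.frame(source = character(), edge_type = character(),
             target = character(), stringsAsFactors = FALSE)
}

.tree_edges <- function(pathosoms) {
  rows <- list()
  for (p in pathosoms) {
    if (!is.null(p$parent)) {
      rows[[length(rows) + 1]] <-
        data.frame(source = p$pathosom_id, edge_type = "is-element-of",
                   target = p$parent, stringsAsFactors = FALSE)
    }
    for (ch in p$children) {
      rows[[length(rows) + 1]] <-
        data.frame(source = p$pathosom_id, edge_type = "has-element",
                   target = ch, stringsAsFactors = FALSE)
    }
    for (v in p$variants) {
      rows[[length(rows) + 1]] <-
        data.frame(source = p$pathosom_id, edge_type = "has-variant",
                   target = v, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_edges())
  do.call(rbind, rows)
}

#' @export
print.knowledge_base <- function(x, ...) {
  nph <- sum(vapply(x$pathosoms, function(p) length(p$pathophems), integer(1)))
  cat(sprintf(
    "<knowledge_base> %d terms, %d pathosoms (%d pathophems), %d edges\n",
    length(x$lexicon), length(x$pathosoms), nph, nrow(x$net$edges)))
  invisible(x)
}

#' @export
print.pathosom <- function(x, ...) {
  cat(sprintf("<pathosom %s> %s: %d pathophems%s\n", x$pathosom_id, x$name,
              length(x$pathophems),
              if (is.null(x$rule)) "" else " + rule"))
  invisible(x)
}

#' @export
print.pathophem <- function(x, ...) {
  attrs <- vapply(x$attributes, function(a)
    paste0(a$name, "=", paste(a$value, collapse = "..")), character(1))
  cat(sprintf("<pathophem> %s [%s]%s\n", x$subject, x$grade,
              if (length(attrs)) paste0(" {", paste(attrs, collapse = ", "), "}")
              else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# KB validation: issues are data, not exceptions.

.issue <- function(entity, invariant, severity, message) {
  data.frame(entity = entity, invariant = invariant, severity = severity,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a knowledge base
#'
#' Checks every type invariant and the referential integrity across the
#' lexicon, the pathosom pool and the semantic network: code patterns,
#' label presence, attribute arity and shape, grade symbols, explicit
#' probabilities, rule syntax, tree-link reciprocity and acyclicity,
#' edge endpoints, and thesaurus enums. Class codes outside the packaged
#' taxonomy are warnings (user KBs may extend it); everything else is an
#' error.
#'
#' @param kb A [knowledge_base()].
#' @return A data.frame of class `kb_validation` with columns `entity`,
#'   `invariant`, `severity` (`"error"`/`"warning"`) and `message`; zero
#'   rows iff the KB is fully valid.
#' @export
validate_kb <- function(kb) {
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x
  known_classes <- class_table()$code
  tcodes <- names(kb$lexicon)

  for (t in kb$lexicon) {
    ent <- paste0("term:", t$term_code)
    if (!grepl(.term_code_pattern, t$term_code)) {
      add(.issue(ent, "code-pattern", "error", "term code violates pattern"))
    }
    if (nrow(t$labels) < 1) {
      add(.issue(ent, "label-presence", "error", "term has no label"))
    }
    if (!all(t$labels$language %in% .languages)) {
      add(.issue(ent, "label-language", "error", "unknown label language"))
    }
    if (!(t$class_code %in% known_classes)) {
      add(.issue(ent, "unknown-class", "warning",
                 paste0("class code ", t$class_code,
                        " not in the packaged class table")))
    }
    for (x in t$xrefs) {
      if (!(x$thesaurus %in% .thesauri) || !nzchar(x$code)) {
        add(.issue(ent, "xref", "error", "invalid thesaurus reference"))
      }
    }
  }

  for (p in kb$pathosoms) {
    ent <- paste0("pathosom:", p$pathosom_id)
    for (ph in p$pathophems) {
      if (length(ph$attributes) > 3) {
        add(.issue(ent, "attribute-arity", "error",
                   paste0("pathophem ", ph$subject, " carries ",
                          length(ph$attributes), " attributes (max 3)")))
      }
      if (!(ph$subject %in% tcodes)) {
        add(.issue(ent, "subject-resolvable", "error",
                   paste0("pathophem subject ", ph$subject,
                          " not in the lexicon")))
      }
      if (!(ph$grade %in% grade_symbols())) {
        add(.issue(ent, "grade-symbol", "error",
                   paste0("unknown grade ", ph$grade)))
      }
      if (!is.null(ph$prob) &&
          !any(vapply(.grade_table$symbol, function(s)
            .prob_in_grade(ph$prob, s), logical(1)))) {
        add(.issue(ent, "probability-gap", "error",
                   paste0("explicit probability ", ph$prob,
                          " falls in a grade-interval gap")))
      }
      cc <- ph$class_code
      if (!is.null(cc) && !(cc %in% known_classes)) {
        add(.issue(ent, "unknown-class", "warning",
                   paste0("pathophem class code ", cc,
                          " not in the packaged class table")))
      }
    }
    if (!is.null(p$rule)) {
      ok <- tryCatch({ parse_rule(p$rule); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) {
        add(.issue(ent, "rule-syntax", "error", ok))
      }
    }
    if (!is.null(p$parent)) {
      pp <- kb$pathosoms[[p$parent]]
      if (is.null(pp)) {
        add(.issue(ent, "tree-consistency", "error",
                   paste0("parent ", p$parent, " does not exist")))
      } else if (!(p$pathosom_id %in% pp$children)) {
        add(.issue(ent, "tree-consistency", "error",
                   paste0("parent ", p$parent,
                          " does not list this pathosom as a child")))
      }
    }
    for (ch in p$children) {
      cc <- kb$pathosoms[[ch]]
      if (is.null(cc)) {
        add(.issue(ent, "tree-consistency", "error",
                   paste0("child ", ch, " does not exist")))
      } else if (!identical(cc$parent, p$pathosom_id)) {
        add(.issue(ent, "tree-consistency", "error",
                   paste0("child ", ch, " does not point back to this parent")))
      }
    }
    for (v in p$variants) {
      if (is.null(kb$pathosoms[[v]])) {
        add(.issue(ent, "tree-consistency", "error",
                   paste0("variant ", v, " does not exist")))
      }
    }
    # self-ancestry via the parent chain
    seen <- character()
    cur <- p$parent
    while (!is.null(cur)) {
      if (cur == p$pathosom_id) {
        add(.issue(ent, "tree-acyclic", "error",
                   "pathosom is its own ancestor"))
        break
      }
      if (cur %in% seen) break
      seen <- c(seen, cur)
      cur <- kb$pathosoms[[cur]]$parent %||% NULL
    }
  }

  nodes <- kb$net$nodes
  bad <- !(kb$net$edges$source %in% nodes) | !(kb$net$edges$target %in% nodes)
  if (any(bad)) {
    add(.issue("net", "edge-endpoints", "error",
               paste0(sum(bad), " edge(s) with endpoints outside the node set")))
  }
  cyc <- check_acyclic(kb$net)
  for (cy in cyc) {
    add(.issue("net", "hierarchy-acyclic", "error",
               paste0("hierarchical cycle: ", paste(cy, collapse = " -> "))))
  }

  out <- if (length(issues)) do.call(rbind, issues) else
    .issue(character(), character(), character(), character())[0, ]
  class(out) <- c("kb_validation", class(out))
  out
}

#' @export
print.kb_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("knowledge base valid: no issues\n")
  } else {
    cat(nrow(x), "issue(s):\n")
    print.data.frame(x)
  }
  invisible(x)
}
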