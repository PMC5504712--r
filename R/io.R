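# Knowledge-base serialization (canonical single-file JSON), lexicon TSV
# import/export, and summary statistics.

.schema_version <- "1.0"

.strip_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, .strip_null)
}

.term_to_rep <- function(t) {
  list(
    term_code = t$term_code,
    labels = unname(lapply(seq_len(nrow(t$labels)), function(i)
      list(language = t$labels$language[i], surface = t$labels$surface[i]))),
    class_code = t$class_code,
    xrefs = unname(lapply(t$xrefs, function(x)
      list(thesaurus = x$thesaurus, code = x$code)))
  )
}

.attr_to_rep <- function(a) {
  list(kind = a$kind, name = a$name, value = a$value,
       unit = a$unit, scale = a$scale)
}

.ph_to_rep <- function(ph) {
  list(subject = ph$subject,
       attributes = unname(lapply(ph$attributes, .attr_to_rep)),
       grade = ph$grade, prob = ph$prob, class_code = ph$class_code)
}

.psm_to_rep <- function(p) {
  list(pathosom_id = p$pathosom_id, name = p$name,
       pathophems = unname(lapply(p$pathophems, .ph_to_rep)),
       rule = p$rule, parent = p$parent,
       children = as.list(p$children), variants = as.list(p$variants),
       xrefs = unname(lapply(p$xrefs, function(x)
         list(thesaurus = x$thesaurus, code = x$code))))
}

#' Save a knowledge base as canonical JSON
#'
#' Single-document JSON with top-level keys `meta`, `lexicon`, `pathosoms`,
#' `edges`. Serialization is canonical — entries sorted by code, stable
#' number formatting — so two saves of the same KB are byte-identical and
#' independent of in-memory construction order. An invalid KB (any
#' error-severity issue from [validate_kb()]) is refused.
#'
#' @param kb A [knowledge_base()].
#' @param path Output file path.
#' @export
save_kb <- function(kb, path) {
  issues <- validate_kb(kb)
  if (any(issues$severity == "error")) {
    print(issues)
    stop("refusing to save an invalid knowledge base", call. = FALSE)
  }
  rep <- list(
    meta = list(schema_version = .schema_version),
    lexicon = lapply(kb$lexicon, .term_to_rep),
    pathosoms = lapply(kb$pathosoms, .psm_to_rep),
    edges = unname(lapply(seq_len(nrow(kb$net$edges)), function(i)
      list(source = kb$net$edges$source[i],
           edge_type = kb$net$edges$edge_type[i],
           target = kb$net$edges$target[i])))
  )
  json <- jsonlite::toJSON(.strip_null(rep), pretty = TRUE,
                           auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

.attr_from_rep <- function(a) {
  val <- a$value
  if (is.list(val)) val <- unlist(val)
  attribute(name = a$name, value = val, kind = a$kind,
            unit = a$unit %||% NULL,
            scale = if (is.null(a$scale)) NULL else unlist(a$scale))
}

.term_from_rep <- function(x) {
  labs <- do.call(rbind, lapply(x$labels, function(l)
    data.frame(language = l$language, surface = l$surface,
               stringsAsFactors = FALSE)))
  atomistic_term(x$term_code, labs, x$class_code,
                 xrefs = lapply(x$xrefs, function(r)
                   thesaurus_ref(r$thesaurus, r$code)))
}

.psm_from_rep <- function(x) {
  pathosom(x$pathosom_id, x$name,
           pathophems = lapply(x$pathophems, function(ph)
             pathophem(ph$subject,
                       grade = ph$grade,
                       attributes = lapply(ph$attributes, .attr_from_rep),
                       prob = ph$prob %||% NULL,
                       class_code = ph$class_code %||% NULL)),
           rule = x$rule %||% NULL,
           parent = x$parent %||% NULL,
           children = as.character(unlist(x$children)),
           variants = as.character(unlist(x$variants)),
           xrefs = lapply(x$xrefs, function(r)
             thesaurus_ref(r$thesaurus, r$code)))
}

#' Load a knowledge base from JSON
#'
#' Reads a file written by [save_kb()], rebuilds the typed objects and runs
#' [validate_kb()]: error-severity issues are fatal, warnings are surfaced
#' as R warnings. Unknown top-level keys are tolerated (forward
#' compatibility, with a warning); an unsupported schema version is an
#' error.
#'
#' @param path Input file path.
#' @return A [knowledge_base()].
#' @export
load_kb <- function(path) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse KB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  known <- c("meta", "lexicon", "pathosoms", "edges")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown top-level key(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  ver <- raw$meta$schema_version %||% NA_character_
  if (!identical(ver, .schema_version)) {
    stop("unsupported KB schema version: ", ver, " (expected ",
         .schema_version, ")", call. = FALSE)
  }
  terms <- lapply(raw$lexicon, .term_from_rep)
  psms <- lapply(raw$pathosoms, .psm_from_rep)
  edges <- if (length(raw$edges)) {
    do.call(rbind, lapply(raw$edges, function(e)
      data.frame(source = e$source, edge_type = e$edge_type,
                 target = e$target, stringsAsFactors = FALSE)))
  } else NULL
  kb <- knowledge_base(unname(terms), unname(psms), edges)
  issues <- validate_kb(kb)
  if (any(issues$severity == "error")) {
    print(issues)
    stop("KB failed validation on load: ",
         sum(issues$severity == "error"), " error(s)", call. = FALSE)
  }
  for (m in issues$message[issues$severity == "warning"]) {
    warning(m, call. = FALSE)
  }
  kb
}

#' Knowledge-base summary statistics
#'
#' Counts of pathosoms, pathophems, terms and edges, plus pathophem counts
#' per class code (a pathophem without its own class code inherits its
#' subject term's class).
#'
#' @param kb A [knowledge_base()].
#' @return A list of class `kb_stats`.
#' @export
kb_stats <- function(kb) {
  classes <- integer()
  nph <- 0L
  for (p in kb$pathosoms) {
    for (ph in p$pathophems) {
      nph <- nph + 1L
      cc <- ph$class_code %||% kb$lexicon[[ph$subject]]$class_code %||%
        NA_integer_
      key <- as.character(cc)
      classes[key] <- (if (key %in% names(classes)) classes[[key]] else 0L) + 1L
    }
  }
  if (length(classes)) classes <- classes[order(names(classes))]
  structure(list(n_pathosoms = length(kb$pathosoms), n_pathophems = nph,
                 n_terms = length(kb$lexicon), n_edges = nrow(kb$net$edges),
                 per_class = classes),
            class = "kb_stats")
}

#' @export
print.kb_stats <- function(x, ...) {
  cat(sprintf("pathosoms: %d\npathophems: %d\nterms: %d\nedges: %d\n",
              x$n_pathosoms, x$n_pathophems, x$n_terms, x$n_edges))
  if (length(x$per_class)) {
    cat("pathophems per class code:\n")
    print(x$per_class)
  }
  invisible(x)
}

#' Read/write a lexicon as TSV
#'
#' UTF-8, tab-separated, header row, no quoting; one row per label x xref
#' combination (columns `term_code`, `language`, `label`, `class_code`,
#' `thesaurus`, `xref_code`; the xref columns are empty for terms without
#' cross-references).
#'
#' @param path File path.
#' @param lexicon List of [atomistic_term()] (for writing); a
#'   [knowledge_base()] is also accepted.
#' @return `read_lexicon_tsv()` returns a list of [atomistic_term()].
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  if (inherits(lexicon, "knowledge_base")) lexicon <- lexicon$lexicon
  rows <- list()
  for (t in lexicon) {
    xr <- if (length(t$xrefs)) t$xrefs else list(NULL)
    for (i in seq_len(nrow(t$labels))) {
      for (x in xr) {
        rows[[length(rows) + 1L]] <- data.frame(
          term_code = t$term_code, language = t$labels$language[i],
          label = t$labels$surface[i], class_code = t$class_code,
          thesaurus = if (is.null(x)) "" else x$thesaurus,
          xref_code = if (is.null(x)) "" else x$code,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", encoding = "UTF-8")
  lapply(split(tab, tab$term_code), function(g) {
    labs <- unique(g[, c("language", "label")])
    xr <- unique(g[nzchar(g$thesaurus), c("thesaurus", "xref_code")])
    atomistic_term(
      g$term_code[1],
      data.frame(language = labs$language, surface = labs$label,
                 stringsAsFactors = FALSE),
      as.integer(g$class_code[1]),
      xrefs = lapply(seq_len(nrow(xr)), function(i)
        thesaurus_ref(xr$thesaurus[i], xr$xref_code[i])))
  })
}
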