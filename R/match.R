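# The linguistic game: verify a patient vector, match it against the
# pathosom pool, rank, roll up equal-evidence subtrees, broaden empty
# queries, narrow large candidate sets, and drive the dialogue loop.

.level_factors <- c(exact = 1.0, `attribute-relaxed` = 0.8, generalized = 0.6)

#' Query configuration
#'
#' Thresholds and switches of the matching engine. The engine is fully
#' deterministic: identical KB, query, configuration and dialogue answers
#' produce identical results and transcript.
#'
#' @param mode `"strict"` (an attributed query element never matches an
#'   attribute-free pathophem) or `"relaxed"` (it does).
#' @param roll_up Collapse a pathosom subtree to its most general member
#'   when ancestor and descendants match with identical evidence.
#' @param min_results Broaden when fewer candidates than this remain.
#' @param max_results Narrow (ask a question) when more than this remain.
#' @param max_broaden_steps Hop limit for semantic-network generalization.
#' @export
query_config <- function(mode = c("strict", "relaxed"), roll_up = TRUE,
                         min_results = 1, max_results = 10,
                         max_broaden_steps = 2) {
  mode <- match.arg(mode)
  stopifnot(min_results <= max_results, max_broaden_steps >= 1)
  structure(list(mode = mode, roll_up = roll_up,
                 min_results = as.integer(min_results),
                 max_results = as.integer(max_results),
                 max_broaden_steps = as.integer(max_broaden_steps)),
            class = "query_config")
}

#' Patient vector
#'
#' The query: one to five elements, each a term (surface string or term
#' code) with at most three attributes.
#'
#' @param ... Elements: [query_element()] objects or plain strings
#'   (shorthand for an attribute-free element).
#' @export
patient_vector <- function(...) {
  elements <- lapply(list(...), function(e) {
    if (is.character(e)) query_element(e) else e
  })
  if (length(elements) < 1 || length(elements) > 5) {
    stop("a patient vector has between 1 and 5 elements", call. = FALSE)
  }
  for (e in elements) stopifnot(inherits(e, "query_element"))
  structure(elements, class = "patient_vector")
}

#' @rdname patient_vector
#' @param term Surface string (resolved via [resolve_term()]) or a term code.
#' @param attributes List of at most three [attribute()] objects.
#' @export
query_element <- function(term, attributes = list()) {
  stopifnot(is.character(term), length(term) == 1, nzchar(term))
  if (length(attributes) > 3) {
    stop("a query element carries at most 3 attributes", call. = FALSE)
  }
  if (inherits(attributes, "kb_attribute")) attributes <- list(attributes)
  for (a in attributes) stopifnot(inherits(a, "kb_attribute"))
  structure(list(term = term, term_code = NULL, attributes = attributes,
                 dropped = integer(), general = character()),
            class = "query_element")
}

#' @export
print.patient_vector <- function(x, ...) {
  cat("<patient_vector>\n")
  for (i in seq_along(x)) {
    e <- x[[i]]
    attrs <- vapply(e$attributes, function(a)
      paste0(a$name, "=", paste(a$value, collapse = "..")), character(1))
    cat(sprintf("  %d. %s%s%s\n", i, e$term,
                if (!is.null(e$term_code) && !identical(e$term, e$term_code))
                  paste0(" [", e$term_code, "]") else "",
                if (length(attrs)) paste0(" {", paste(attrs, collapse = ", "),
                                          "}") else ""))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Verification (syntactic analysis of the patient vector)

#' Verify a patient vector against a knowledge base
#'
#' Syntactic analysis: every surface string is replaced by a term code via
#' [resolve_term()]; ambiguous or unresolvable elements are reported as
#' issues carrying the candidate suggestions. A resolved term must also have
#' a "primary meaning": a hierarchical attachment in the semantic network or
#' use by at least one pathophem.
#'
#' @param pv A [patient_vector()].
#' @param kb A [knowledge_base()].
#' @param language Optional language tag restricting label matching.
#' @return List of class `vector_verification` with fields `ok` (logical),
#'   `vector` (the resolved [patient_vector()], elements with issues left
#'   unresolved) and `issues` (data.frame `element`, `surface`, `issue`,
#'   `suggestions`). An entirely unresolvable vector is an error.
#' @export
verify_vector <- function(pv, kb, language = NULL) {
  stopifnot(inherits(pv, "patient_vector"))
  issues <- list()
  used_subjects <- unique(unlist(lapply(kb$pathosoms, function(p)
    vapply(p$pathophems, `[[`, character(1), "subject"))))
  add_issue <- function(i, surface, what, sugg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      element = i, surface = surface, issue = what,
      suggestions = paste(sugg, collapse = ","), stringsAsFactors = FALSE)
  }
  for (i in seq_along(pv)) {
    e <- pv[[i]]
    if (grepl(.term_code_pattern, e$term) && e$term %in% names(kb$lexicon)) {
      code <- e$term
    } else {
      res <- resolve_term(e$term, kb, language = language)
      exact <- res[res$match_kind == "exact-label", , drop = FALSE]
      if (nrow(exact) == 1) {
        code <- exact$term_code
      } else if (nrow(exact) > 1) {
        add_issue(i, e$term, "ambiguous", exact$term_code)
        next
      } else {
        add_issue(i, e$term, "unresolvable",
                  res$term_code[res$match_kind == "fuzzy-suggestion"])
        next
      }
    }
    # "primary meaning": hierarchically attached or used by a pathophem
    attached <- any(kb$net$edges$source == code &
                      kb$net$edges$edge_type %in% .hier_types) ||
      code %in% used_subjects
    if (!attached) {
      add_issue(i, e$term, "no-primary-meaning", character())
      next
    }
    pv[[i]]$term_code <- code
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(element = integer(), surface = character(),
               issue = character(), suggestions = character(),
               stringsAsFactors = FALSE)
  resolved <- !vapply(pv, function(e) is.null(e$term_code), logical(1))
  if (!any(resolved)) {
    stop("empty query: no element of the patient vector could be resolved",
         call. = FALSE)
  }
  structure(list(ok = nrow(issues) == 0, vector = pv, issues = issues),
            class = "vector_verification")
}

.ensure_resolved <- function(pv, kb) {
  stopifnot(inherits(pv, "patient_vector"))
  if (all(!vapply(pv, function(e) is.null(e$term_code), logical(1)))) {
    return(pv)
  }
  v <- verify_vector(pv, kb)
  if (!v$ok) {
    stop("unresolved query element(s): ",
         paste(v$issues$surface, collapse = ", "), call. = FALSE)
  }
  v$vector
}

# ---------------------------------------------------------------------------
# Attribute compatibility and the element/pathophem match predicate

.attr_compatible <- function(qa, pa) {
  if (pa$kind == "numeric") {
    if (!is.numeric(qa$value)) return(FALSE)
    if (!is.null(qa$unit) && !is.null(pa$unit) &&
        !identical(qa$unit, pa$unit)) return(FALSE)
    pv <- pa$value
    qv <- qa$value
    if (length(pv) == 2) {
      if (length(qv) == 1) return(qv >= pv[1] && qv < pv[2])
      return(qv[1] >= pv[1] && qv[2] <= pv[2])
    }
    if (length(qv) == 1) return(qv == pv)
    return(FALSE)
  }
  if (pa$kind == "ordinal") {
    sc <- pa$scale
    qi <- match(qa$value, sc)
    pi <- match(pa$value, sc)
    if (is.na(qi) || is.na(pi)) return(FALSE)
    return(qi >= pi)  # pathophem value is the minimum level
  }
  # cardinal
  identical(.normalize_surface(as.character(qa$value)),
            .normalize_surface(as.character(pa$value)))
}

# relaxed forgives a query attribute with no same-name counterpart on the
# pathophem (including the attribute-free pathophem); a counterpart that
# exists must always be compatible
.attrs_compatible <- function(qattrs, phattrs, relaxed) {
  if (!length(qattrs)) return(TRUE)
  ph_names <- vapply(phattrs, `[[`, character(1), "name")
  for (qa in qattrs) {
    j <- match(qa$name, ph_names)
    if (is.na(j)) {
      if (!relaxed) return(FALSE)
    } else if (!.attr_compatible(qa, phattrs[[j]])) {
      return(FALSE)
    }
  }
  TRUE
}

# best match of one query element against the pathophems of one pathosom;
# returns NULL or list(pathophem index, level, weight, grade)
.match_element <- function(el, psm, kb, relaxed) {
  syn <- .syn_closure(el$term_code, kb$net)
  gen <- el$general
  remaining <- if (length(el$dropped)) el$attributes[-el$dropped]
               else el$attributes
  best <- NULL
  for (j in seq_along(psm$pathophems)) {
    ph <- psm$pathophems[[j]]
    if (ph$grade == "NOT") next
    level <- NULL
    if (ph$subject %in% syn) {
      if (.attrs_compatible(el$attributes, ph$attributes, relaxed)) {
        level <- "exact"
      } else if (length(el$dropped) &&
                 .attrs_compatible(remaining, ph$attributes, relaxed)) {
        level <- "attribute-relaxed"
      }
    } else if (length(gen) && ph$subject %in% gen &&
               .attrs_compatible(remaining, ph$attributes, relaxed)) {
      level <- "generalized"
    }
    if (is.null(level)) next
    w <- .ph_weight(ph) * .level_factors[[level]]
    if (is.null(best) || w > best$weight) {
      best <- list(pathophem = j, subject = ph$subject, level = level,
                   weight = w, grade = ph$grade)
    }
  }
  best
}

# NOT exclusion: any excluding pathophem matched by any query element
.excluded_by <- function(psm, pv, kb) {
  for (ph in psm$pathophems) {
    if (ph$grade != "NOT") next
    for (el in pv) {
      if (is.null(el$term_code)) next
      syn <- .syn_closure(el$term_code, kb$net)
      if (ph$subject %in% syn &&
          .attrs_compatible(el$attributes, ph$attributes, relaxed = TRUE)) {
        return(ph)
      }
    }
  }
  NULL
}

.match_candidates <- function(pv, kb, relaxed) {
  ids <- character()
  for (psm in kb$pathosoms) {
    if (!is.null(.excluded_by(psm, pv, kb))) next
    ok <- TRUE
    for (el in pv) {
      if (is.null(el$term_code) ||
          is.null(.match_element(el, psm, kb, relaxed))) {
        ok <- FALSE
        break
      }
    }
    if (ok) ids <- c(ids, psm$pathosom_id)
  }
  sort(ids)
}

#' Strict conjunctive match
#'
#' Returns the pathosoms for which every query element matches some
#' pathophem (same subject after synonym closure and attribute-compatible:
#' a numeric query value inside the pathophem's range, categories equal,
#' ordinal at or above the pathophem's minimum level), minus pathosoms
#' excluded by a `NOT`-graded pathophem matching any query element. In
#' `"strict"` mode an attributed query element never matches an
#' attribute-free pathophem.
#'
#' @param pv A [patient_vector()]; resolved automatically if needed.
#' @param kb A [knowledge_base()].
#' @param config A [query_config()]; only `mode` is consulted.
#' @return Sorted character vector of pathosom ids.
#' @export
match_strict <- function(pv, kb, config = query_config()) {
  pv <- .ensure_resolved(pv, kb)
  .match_candidates(pv, kb, relaxed = config$mode == "relaxed")
}

# ---------------------------------------------------------------------------
# Ranking and roll-up

#' Rank candidate pathosoms
#'
#' Scores each candidate as the sum over matched query elements of the
#' matching pathophem's grade weight (or explicit probability) times a
#' match-level factor (exact 1.0, attribute-relaxed 0.8, generalized 0.6),
#' divided by the query length. Ordered by descending score, then by more
#' Lead-grade matches, then lexicographic pathosom id.
#'
#' @param candidates Character vector of pathosom ids.
#' @param pv The resolved [patient_vector()].
#' @param kb A [knowledge_base()].
#' @param config A [query_config()].
#' @return A `match_results` list of `match_result` objects.
#' @export
rank_candidates <- function(candidates, pv, kb, config = query_config()) {
  pv <- .ensure_resolved(pv, kb)
  relaxed <- config$mode == "relaxed"
  results <- lapply(candidates, function(id) {
    psm <- kb$pathosoms[[id]]
    if (is.null(psm)) stop("unknown pathosom id: ", id, call. = FALSE)
    rows <- list()
    missing <- integer()
    for (i in seq_along(pv)) {
      m <- .match_element(pv[[i]], psm, kb, relaxed)
      if (is.null(m)) {
        missing <- c(missing, i)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          element = i, term_code = pv[[i]]$term_code, subject = m$subject,
          grade = m$grade, level = m$level, weight = m$weight,
          stringsAsFactors = FALSE)
      }
    }
    matched <- if (length(rows)) do.call(rbind, rows) else
      data.frame(element = integer(), term_code = character(),
                 subject = character(), grade = character(),
                 level = character(), weight = numeric(),
                 stringsAsFactors = FALSE)
    structure(list(pathosom_id = id, name = psm$name,
                   score = sum(matched$weight) / length(pv),
                   matched = matched, missing = missing,
                   excluded_by = NULL, trace = character()),
              class = "match_result")
  })
  lead_n <- vapply(results, function(r) sum(r$matched$grade == "Lead"),
                   integer(1))
  score <- vapply(results, `[[`, numeric(1), "score")
  ids <- vapply(results, `[[`, character(1), "pathosom_id")
  results <- results[order(-score, -lead_n, ids)]
  structure(results, class = "match_results")
}

#' @export
as.data.frame.match_results <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(pathosom_id = character(), name = character(),
                      score = numeric(), n_matched = integer(),
                      n_missing = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    pathosom_id = vapply(x, `[[`, character(1), "pathosom_id"),
    name = vapply(x, `[[`, character(1), "name"),
    score = vapply(x, `[[`, numeric(1), "score"),
    n_matched = vapply(x, function(r) nrow(r$matched), integer(1)),
    n_missing = vapply(x, function(r) length(r$missing), integer(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.match_results <- function(x, ...) {
  if (!length(x)) {
    cat("no matching pathosoms\n")
    return(invisible(x))
  }
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

.ancestors <- function(id, kb) {
  out <- character()
  cur <- kb$pathosoms[[id]]$parent %||% NULL
  while (!is.null(cur) && !(cur %in% out)) {
    out <- c(out, cur)
    cur <- kb$pathosoms[[cur]]$parent %||% NULL
  }
  out
}

#' Roll equal-evidence subtrees up to their most general member
#'
#' When a pathosom and any of its tree descendants both match with the same
#' set of query elements, the descendants are removed and the most general
#' representative kept: the reported set is an antichain of the pathosom
#' tree within each equal-evidence group.
#'
#' @param results A `match_results` list (ranked).
#' @param kb A [knowledge_base()].
#' @return The filtered `match_results`, order preserved.
#' @export
roll_up <- function(results, kb) {
  if (!length(results)) return(results)
  ids <- vapply(results, `[[`, character(1), "pathosom_id")
  sig <- vapply(results, function(r)
    paste(sort(unique(r$matched$element)), collapse = ","), character(1))
  keep <- rep(TRUE, length(results))
  for (i in seq_along(results)) {
    anc <- intersect(.ancestors(ids[i], kb), ids)
    if (length(anc) && any(sig[match(anc, ids)] == sig[i])) {
      keep[i] <- FALSE
    }
  }
  structure(results[keep], class = "match_results")
}

# ---------------------------------------------------------------------------
# Broadening (relaxation) and narrowing (question selection)

# stage-1 drop order: cardinal qualifiers are the most specific, numeric
# (typically demographic ranges) the least; within a kind, element order
# then declaration order
.attr_drop_order <- function(pv) {
  rows <- list()
  pri <- c(cardinal = 1L, ordinal = 2L, numeric = 3L)
  for (i in seq_along(pv)) {
    for (j in seq_along(pv[[i]]$attributes)) {
      a <- pv[[i]]$attributes[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        element = i, attr = j, pri = pri[[a$kind]], name = a$name,
        value = paste(a$value, collapse = ".."), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  tab[order(tab$pri, tab$element, tab$attr), , drop = FALSE]
}

#' Broaden a patient vector
#'
#' Staged relaxation, re-running the match after every step: stage 1 drops
#' query attributes one at a time (most specific first; matches made without
#' a dropped attribute are level `attribute-relaxed`); stage 2 expands each
#' term through [generalize()] and accepts matches on the broader terms
#' (level `generalized`). Stages run until the candidate count reaches
#' `config$min_results` or relaxations are exhausted; `force = TRUE` applies
#' all of stage 1 even when the strict result already suffices (useful for
#' inspecting the neighborhood of a unique diagnosis). The relaxed candidate
#' set is always a superset of the strict set.
#'
#' @param pv A [patient_vector()].
#' @param kb A [knowledge_base()].
#' @param config A [query_config()].
#' @param force Apply stage 1 in full even if no broadening is needed.
#' @return List with `candidates` (ids), `vector` (the annotated, relaxed
#'   patient vector for [rank_candidates()]), and `trace` (character vector
#'   of relaxation steps).
#' @export
broaden <- function(pv, kb, config = query_config(), force = FALSE) {
  pv <- .ensure_resolved(pv, kb)
  relaxed <- config$mode == "relaxed"
  ids <- .match_candidates(pv, kb, relaxed)
  trace <- character()
  if (length(ids) >= config$min_results && !force) {
    return(list(candidates = ids, vector = pv, trace = trace))
  }
  need <- function() length(ids) < config$min_results
  started_below <- need()

  ord <- .attr_drop_order(pv)
  if (!is.null(ord)) {
    for (k in seq_len(nrow(ord))) {
      if (started_below && !need()) break
      i <- ord$element[k]
      pv[[i]]$dropped <- c(pv[[i]]$dropped, ord$attr[k])
      trace <- c(trace, sprintf("drop-attribute: element %d %s=%s",
                                i, ord$name[k], ord$value[k]))
      ids <- .match_candidates(pv, kb, relaxed)
    }
  }
  if (need()) {
    for (i in seq_along(pv)) {
      g <- generalize(pv[[i]]$term_code, kb$net,
                      max_steps = config$max_broaden_steps)
      g <- sort(unique(unlist(lapply(g, .syn_closure, net = kb$net))))
      g <- setdiff(g, .syn_closure(pv[[i]]$term_code, kb$net))
      if (length(g)) {
        pv[[i]]$general <- g
        trace <- c(trace, sprintf("generalize: element %d %s -> %s",
                                  i, pv[[i]]$term_code,
                                  paste(g, collapse = ",")))
      }
    }
    ids <- .match_candidates(pv, kb, relaxed)
  }
  list(candidates = ids, vector = pv, trace = trace)
}

#' Suggest the most discriminating next question
#'
#' Among the (non-excluding) pathophems of the candidates whose subject is
#' not already in the query, selects the one whose presence count `c` across
#' the `n` candidates minimizes `|c - n/2|` — the question whose answer
#' splits the candidate set most evenly. Ties break toward higher grade
#' weight, then term-code order.
#'
#' @param candidates Character vector of pathosom ids (length > 1).
#' @param pv The resolved [patient_vector()].
#' @param kb A [knowledge_base()].
#' @param exclude Subjects never to suggest again (e.g. already asked).
#' @return A list of class `pathophem_suggestion` with `term_code`,
#'   `attributes` and `grade` of a representative pathophem, or `NULL` when
#'   every askable subject is exhausted.
#' @export
narrow_suggest <- function(candidates, pv, kb, exclude = character()) {
  if (length(candidates) < 2) {
    stop("nothing to ask: need more than one candidate", call. = FALSE)
  }
  pv <- .ensure_resolved(pv, kb)
  pv_subjects <- unique(unlist(lapply(pv, function(e)
    .syn_closure(e$term_code, kb$net))))
  n <- length(candidates)
  stats <- new.env(parent = emptyenv())
  for (id in candidates) {
    psm <- kb$pathosoms[[id]]
    seen <- character()
    for (ph in psm$pathophems) {
      s <- ph$subject
      if (ph$grade == "NOT" || s %in% pv_subjects || s %in% exclude) next
      rec <- stats[[s]] %||% list(count = 0L, weight = -1, rep = NULL)
      if (!(s %in% seen)) {
        rec$count <- rec$count + 1L
        seen <- c(seen, s)
      }
      w <- .ph_weight(ph)
      if (w > rec$weight) {
        rec$weight <- w
        rec$rep <- ph
      }
      stats[[s]] <- rec
    }
  }
  subjects <- sort(ls(stats))
  if (!length(subjects)) return(NULL)
  split <- vapply(subjects, function(s) abs(stats[[s]]$count - n / 2),
                  numeric(1))
  weight <- vapply(subjects, function(s) stats[[s]]$weight, numeric(1))
  best <- subjects[order(split, -weight, subjects)][1]
  rep_ph <- stats[[best]]$rep
  structure(list(term_code = best, attributes = rep_ph$attributes,
                 grade = rep_ph$grade),
            class = "pathophem_suggestion")
}

#' @export
print.pathophem_suggestion <- function(x, ...) {
  attrs <- vapply(x$attributes, function(a)
    paste0(a$name, "=", paste(a$value, collapse = "..")), character(1))
  cat(sprintf("ask about: %s%s [%s]\n", x$term_code,
              if (length(attrs)) paste0(" {", paste(attrs, collapse = ", "),
                                        "}") else "", x$grade))
  invisible(x)
}

# ---------------------------------------------------------------------------
# The dialogue loop and one-shot query

#' One-shot query
#'
#' Verify, match strictly, broaden if the candidate set falls below
#' `config$min_results`, rank, and (optionally) roll up. This is the
#' non-interactive core of the dialogue.
#'
#' @inheritParams match_strict
#' @return A `match_results` list; the relaxation trace (if any) is attached
#'   as attribute `"trace"`.
#' @export
run_query <- function(pv, kb, config = query_config()) {
  pv <- .ensure_resolved(pv, kb)
  b <- broaden(pv, kb, config)
  results <- rank_candidates(b$candidates, b$vector, kb, config)
  if (config$roll_up) results <- roll_up(results, kb)
  attr(results, "trace") <- b$trace
  results
}

#' Interactive diagnostic dialogue
#'
#' The continuous dialogue of the linguistic game: verify the vector, match;
#' while the candidate set is larger than `config$max_results`, ask the most
#' discriminating question ([narrow_suggest()]) and apply the answer — TRUE
#' appends the finding to the patient vector (up to the 5-element limit),
#' FALSE removes candidates for which that finding is Lead-graded (a Lead
#' finding is always present, so its absence refutes the prototype; lower
#' grades are probabilistic and survive a FALSE), NA retires the question;
#' when the set falls below `config$min_results` it is broadened once.
#' Terminates when the count is within `[min_results, max_results]` or no
#' move remains. Deterministic given the answer sequence.
#'
#' @inheritParams match_strict
#' @param answer_provider Function taking a `pathophem_suggestion` and
#'   returning `TRUE`, `FALSE` or `NA`.
#' @return List with `results` (final ranked `match_results`) and
#'   `transcript` (data.frame `step`, `action`, `detail`, `answer`,
#'   `n_candidates`).
#' @export
dialogue <- function(pv, kb, config = query_config(),
                     answer_provider = function(sug) NA) {
  pv <- .ensure_resolved(pv, kb)
  relaxed <- config$mode == "relaxed"
  asked <- character()
  excluded <- character()
  broadened <- FALSE
  steps <- list()
  log_step <- function(action, detail, answer, n) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = length(steps) + 1L, action = action, detail = detail,
      answer = answer, n_candidates = n, stringsAsFactors = FALSE)
  }
  final <- NULL
  for (iter in seq_len(100L)) {
    ids <- setdiff(.match_candidates(pv, kb, relaxed), excluded)
    results <- rank_candidates(ids, pv, kb, config)
    if (config$roll_up) results <- roll_up(results, kb)
    final <- results
    count <- length(results)
    if (count > config$max_results) {
      sug <- narrow_suggest(ids, pv, kb, exclude = asked)
      if (is.null(sug)) break
      asked <- c(asked, sug$term_code)
      ans <- answer_provider(sug)
      log_step("ask", sug$term_code, as.character(ans), count)
      if (isTRUE(ans)) {
        if (length(pv) >= 5) break
        el <- query_element(sug$term_code)
        el$term_code <- sug$term_code
        pv <- structure(c(unclass(pv), list(el)), class = "patient_vector")
      } else if (isFALSE(ans)) {
        lead_req <- vapply(ids, function(id) {
          any(vapply(kb$pathosoms[[id]]$pathophems, function(ph)
            ph$grade == "Lead" &&
              sug$term_code %in% .syn_closure(ph$subject, kb$net),
            logical(1)))
        }, logical(1))
        excluded <- c(excluded, ids[lead_req])
      }
      # NA: the subject is retired via `asked`
    } else if (count < config$min_results && !broadened) {
      b <- broaden(pv, kb, config)
      pv <- b$vector
      broadened <- TRUE
      log_step("broaden", paste(b$trace, collapse = "; "), NA_character_,
               length(b$candidates))
    } else {
      break
    }
  }
  transcript <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), action = character(), detail = character(),
               answer = character(), n_candidates = integer(),
               stringsAsFactors = FALSE)
  list(results = final, transcript = transcript)
}

#' Evaluate a set of cases against a knowledge base
#'
#' Runs [run_query()] on each case and reports the identification rate (the
#' expected pathosom — or, under roll-up, one of its tree ancestors —
#' appears in the final results) and the median number of proposals (lower
#' median for even counts).
#'
#' @param cases List of cases, each `list(vector =, expected =)` where
#'   `vector` is a [patient_vector()] (or a `synthetic_patient`, whose
#'   source pathosom is then the default `expected`).
#' @param kb A [knowledge_base()].
#' @param config A [query_config()].
#' @return List with `identification_rate`, `median_proposal_count` and
#'   `cases` (per-case data.frame with the proposal count, identification
#'   flag and rank of the expected pathosom).
#' @export
evaluate_cases <- function(cases, kb, config = query_config()) {
  stopifnot(length(cases) > 0)
  rows <- lapply(seq_along(cases), function(k) {
    cs <- cases[[k]]
    if (inherits(cs, "synthetic_patient")) {
      cs <- list(vector = cs$vector, expected = cs$source)
    }
    res <- run_query(cs$vector, kb, config)
    ids <- vapply(res, `[[`, character(1), "pathosom_id")
    hits <- cs$expected
    if (config$roll_up) hits <- c(hits, .ancestors(cs$expected, kb))
    pos <- which(ids %in% hits)
    data.frame(case = k, expected = cs$expected, n_proposals = length(ids),
               identified = length(pos) > 0,
               rank = if (length(pos)) min(pos) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  counts <- sort(tab$n_proposals)
  list(identification_rate = mean(tab$identified),
       median_proposal_count = counts[ceiling(n / 2)],
       cases = tab)
}
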