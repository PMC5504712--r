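# Typed directed semantic network over term (and pathosom) codes:
# synonym resolution, generalization for query broadening, acyclicity.

.edge_types <- c("is-a", "is-part-of", "has-attribute-of", "is-class-of",
                 "synonym-of", "is-element-of", "has-element", "has-variant")
# types whose subgraph must be a DAG (guarantees generalization terminates)
.hier_types <- c("is-a", "is-part-of", "is-class-of", "is-element-of")
# types followed by generalize(): they change granularity, not meaning
# (has-attribute-of is deliberately excluded)
.broaden_types <- c("is-a", "is-part-of", "is-class-of")

#' Typed semantic network
#'
#' A directed graph whose vertices are term codes (and pathosom ids) and
#' whose edges carry one of the relation types `is-a`, `is-part-of`,
#' `has-attribute-of`, `is-class-of`, `synonym-of`, `is-element-of`,
#' `has-element`, `has-variant`. `synonym-of` is symmetric: stored once,
#' queried both ways. The subgraph of hierarchical types must be acyclic.
#'
#' @param edges data.frame with character columns `source`, `edge_type`,
#'   `target`.
#' @param nodes Optional character vector of node codes; defaults to the
#'   edge endpoints.
#' @export
semantic_net <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) edges <- .empty_edges()
  stopifnot(all(c("source", "edge_type", "target") %in% names(edges)))
  edges <- data.frame(source = as.character(edges$source),
                      edge_type = as.character(edges$edge_type),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  bad <- setdiff(unique(edges$edge_type), .edge_types)
  if (length(bad)) {
    stop("unknown edge type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  loops <- edges$edge_type %in% .hier_types & edges$source == edges$target
  if (any(loops)) {
    stop("hierarchical self-loop on ",
         paste(unique(edges$source[loops]), collapse = ", "), call. = FALSE)
  }
  nodes <- sort(unique(c(nodes, edges$source, edges$target)))
  edges <- edges[order(edges$source, edges$edge_type, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "semantic_net")
}

#' @export
print.semantic_net <- function(x, ...) {
  cat(sprintf("<semantic_net> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(table(x$edges$edge_type))
  invisible(x)
}

.net_subgraph <- function(net, types) {
  e <- net$edges[net$edges$edge_type %in% types, , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("source", "target")], directed = TRUE,
                                vertices = net$nodes)
}

# transitive synonym closure of a code (undirected over synonym-of),
# including the code itself
.syn_closure <- function(code, net) {
  e <- net$edges[net$edges$edge_type == "synonym-of", , drop = FALSE]
  if (!nrow(e)) return(code)
  out <- code
  frontier <- code
  repeat {
    nxt <- unique(c(e$target[e$source %in% frontier],
                    e$source[e$target %in% frontier]))
    nxt <- setdiff(nxt, out)
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

#' Detect cycles in the hierarchical subgraph
#'
#' The subgraph restricted to `is-a`, `is-part-of`, `is-class-of` and
#' `is-element-of` edges must be acyclic for generalization to terminate.
#' Synonym and attribute edges are exempt.
#'
#' @param net A [semantic_net()].
#' @return A list of cycles, each a character vector of node codes in cycle
#'   order with the start node repeated at the end; empty iff the
#'   hierarchical subgraph is a DAG.
#' @export
check_acyclic <- function(net) {
  g <- .net_subgraph(net, .hier_types)
  if (igraph::is_dag(g)) return(list())
  comp <- igraph::components(g, mode = "strong")
  cycles <- list()
  for (k in which(comp$csize > 1)) {
    members <- names(comp$membership)[comp$membership == k]
    v <- members[1]
    nb <- names(igraph::neighbors(g, v, mode = "out"))
    nb <- intersect(nb, members)
    sp <- igraph::shortest_paths(g, from = nb[1], to = v, mode = "out")
    cycles[[length(cycles) + 1L]] <- c(v, names(sp$vpath[[1]]))
  }
  cycles
}

#' Generalize a term through the semantic network
#'
#' Breadth-first traversal over outgoing `is-a`, `is-part-of` and
#' `is-class-of` edges, returning broader terms in increasing distance
#' (ties by code), up to `max_steps` hops and excluding the start term.
#' This realizes query broadening: a finding on a finger with no match may
#' still fit a disease prototype described at the level of the hand.
#'
#' @param term A node code of `net`.
#' @param net A [semantic_net()].
#' @param max_steps Positive integer hop limit.
#' @return Character vector of broader codes (possibly empty).
#' @export
generalize <- function(term, net, max_steps = 2) {
  stopifnot(is.numeric(max_steps), max_steps >= 1)
  if (!(term %in% net$nodes)) {
    stop("unknown node: ", deparse(term), call. = FALSE)
  }
  g <- .net_subgraph(net, .broaden_types)
  d <- igraph::distances(g, v = term, mode = "out")[1, ]
  d <- d[is.finite(d) & d > 0 & d <= max_steps]
  if (!length(d)) return(character())
  names(d)[order(d, names(d))]
}

#' Resolve a surface string to term codes
#'
#' Case- and diacritic-insensitive lookup of a label in the KB lexicon.
#' Exact label matches come first, then terms reachable over `synonym-of`
#' edges from an exact match; fuzzy suggestions (normalized edit similarity
#' `>= min_similarity`, at most `max_suggestions`) are produced only when no
#' exact or synonym match exists. Total: any string yields a (possibly
#' empty) result without error.
#'
#' @param surface Non-empty string, e.g. `"renal cyst"` or `"Nierenzyste"`.
#' @param kb A [knowledge_base()].
#' @param language Optional language tag (`"de"`, `"en"`, `"la"`) to
#'   restrict exact matching.
#' @param min_similarity Fuzzy threshold in `[0, 1]` (default 0.8).
#' @param max_suggestions Cap on fuzzy suggestions (default 5).
#' @return data.frame with columns `term_code`, `match_kind`
#'   (`"exact-label"`, `"synonym"`, `"fuzzy-suggestion"`), `label`,
#'   `similarity`.
#' @export
resolve_term <- function(surface, kb, language = NULL,
                         min_similarity = 0.8, max_suggestions = 5) {
  stopifnot(is.character(surface), length(surface) == 1, nzchar(surface))
  labs <- .label_table(kb)
  if (!is.null(language)) labs_exact <- labs[labs$language == language, ]
  else labs_exact <- labs
  q <- .normalize_surface(surface)

  hit <- labs_exact[labs_exact$norm == q, , drop = FALSE]
  out <- list()
  if (nrow(hit)) {
    codes <- sort(unique(hit$term_code))
    out[[1]] <- data.frame(
      term_code = codes, match_kind = "exact-label",
      label = hit$surface[match(codes, hit$term_code)],
      similarity = 1, stringsAsFactors = FALSE)
    syn <- setdiff(sort(unique(unlist(
      lapply(codes, .syn_closure, net = kb$net)))), codes)
    if (length(syn)) {
      out[[2]] <- data.frame(term_code = syn, match_kind = "synonym",
                             label = surface, similarity = 1,
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    return(res)
  }

  if (!nrow(labs)) {
    return(data.frame(term_code = character(), match_kind = character(),
                      label = character(), similarity = numeric(),
                      stringsAsFactors = FALSE))
  }
  d <- utils::adist(q, labs$norm)[1, ]
  sim <- 1 - d / pmax(nchar(q), nchar(labs$norm))
  keep <- which(sim >= min_similarity)
  if (!length(keep)) {
    return(data.frame(term_code = character(), match_kind = character(),
                      label = character(), similarity = numeric(),
                      stringsAsFactors = FALSE))
  }
  cand <- data.frame(term_code = labs$term_code[keep],
                     label = labs$surface[keep], similarity = sim[keep],
                     stringsAsFactors = FALSE)
  # best label per term, then rank by similarity
  cand <- cand[order(-cand$similarity, cand$term_code), , drop = FALSE]
  cand <- cand[!duplicated(cand$term_code), , drop = FALSE]
  cand <- utils::head(cand, max_suggestions)
  res <- data.frame(term_code = cand$term_code,
                    match_kind = "fuzzy-suggestion", label = cand$label,
                    similarity = cand$similarity, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

.normalize_surface <- function(x) {
  # fold German umlauts/eszett explicitly (iconv transliteration of these is
  # platform-dependent), then strip any remaining diacritics
  x <- chartr("äöüÄÖÜ", "aouAOU", x)
  x <- gsub("ß", "ss", x)
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = "")
  x <- gsub("[\"'^`~]", "", x)
  x <- tolower(x)
  gsub("\\s+", " ", trimws(x))
}

.label_table <- function(kb) {
  rows <- lapply(kb$lexicon, function(t) {
    data.frame(term_code = t$term_code, language = t$labels$language,
               surface = t$labels$surface, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(term_code = character(), language = character(),
                      surface = character(), norm = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$norm <- .normalize_surface(tab$surface)
  tab
}

#' Read/write a semantic-network edge list as TSV
#'
#' Columns `source`, `edge_type`, `target`; UTF-8, tab-separated, header
#' row, no quoting.
#'
#' @param path File path.
#' @param net A [semantic_net()] (for writing).
#' @export
read_edges_tsv <- function(path) {
  e <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                         colClasses = "character", encoding = "UTF-8")
  semantic_net(e)
}

#' @rdname read_edges_tsv
#' @export
write_edges_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
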