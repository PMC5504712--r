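# Independent oracles and generators shared across the suite.

# --- Kleene three-valued oracle ---------------------------------------------
# Encodes FALSE=1, NA=2, TRUE=3 and folds with min (AND/SEQ) / max (OR):
# a mechanism deliberately different from the evaluator's all()/any().
oracle_eval <- function(ast, assignment) {
  enc <- function(v) if (is.na(v)) 2L else if (v) 3L else 1L
  dec <- function(k) c(FALSE, NA, TRUE)[k]
  rec <- function(node) {
    if (node$variant == "ATOM") {
      key <- if (is.null(node$flag)) node$code else
        paste(node$code, node$flag)
      return(enc(assignment[[key]]))
    }
    vals <- vapply(node$children, rec, integer(1))
    if (node$variant == "OR") max(vals) else min(vals)
  }
  dec(rec(ast))
}

expr_atom_keys <- function(ast) {
  if (ast$variant == "ATOM") {
    return(if (is.null(ast$flag)) ast$code else paste(ast$code, ast$flag))
  }
  unique(unlist(lapply(ast$children, expr_atom_keys)))
}

# all 3^k tri-state assignments over the given atom keys
all_assignments <- function(keys) {
  grid <- do.call(expand.grid, c(rep(list(c(TRUE, FALSE, NA)), length(keys)),
                                 KEEP.OUT.ATTRS = FALSE))
  names(grid) <- keys
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

# assignment -> FactSet (absent key = not available)
assignment_to_facts <- function(assignment) {
  Filter(Negate(is.na), assignment)
}

# --- random AST generator ----------------------------------------------------
# constraint-free atoms (for evaluator-vs-oracle enumeration)
gen_ast_plain <- function(max_atoms) {
  codes <- sprintf("A%d", seq_len(max_atoms))
  build <- function(budget, depth, top) {
    if (budget <= 1 || depth >= 3 || stats::runif(1) < 0.35) {
      return(list(node = expr_atom(sample(codes, 1)), used = 1L))
    }
    variants <- if (top) c("AND", "OR", "SEQ") else c("AND", "OR")
    variant <- sample(variants, 1)
    k <- sample(2:min(3, budget), 1)
    used <- 0L
    children <- list()
    for (j in seq_len(k)) {
      ch <- build(max(1L, (budget - used) %/% (k - j + 1L)), depth + 1L,
                  top = FALSE)
      children[[j]] <- ch$node
      used <- used + ch$used
    }
    list(node = do.call(switch(variant, AND = expr_and, OR = expr_or,
                               SEQ = expr_seq), children),
         used = used)
  }
  build(max_atoms, 0L, top = TRUE)$node
}

# full-featured atoms (flags, range and value constraints) for round-trips
gen_ast_full <- function() {
  gen_atom <- function() {
    code <- paste0(sample(c("", "M", "O"), 1), sample(1:9999, 1))
    flag <- if (stats::runif(1) < 0.25) sample(LETTERS, 1) else NULL
    constraint <- NULL
    u <- stats::runif(1)
    if (u < 0.25) {
      lo <- round(stats::runif(1, 0, 50), 1)
      hi <- lo + round(stats::runif(1, 0.1, 50), 1)
      constraint <- range_constraint(lo, hi,
                                     unit = sample(list("%", NULL), 1)[[1]])
    } else if (u < 0.4) {
      constraint <- if (stats::runif(1) < 0.5) {
        value_constraint(sample(c("firm", "mamma", "acute", "x2"), 1))
      } else {
        value_constraint(sample(1:100, 1),
                         unit = sample(list("%", NULL), 1)[[1]])
      }
    }
    expr_atom(code, flag, constraint)
  }
  build <- function(depth, top) {
    if (depth >= 3 || stats::runif(1) < 0.4) return(gen_atom())
    variant <- sample(if (top) c("AND", "OR", "SEQ") else c("AND", "OR"), 1)
    k <- sample(2:3, 1)
    children <- lapply(seq_len(k), function(j) build(depth + 1L, FALSE))
    do.call(switch(variant, AND = expr_and, OR = expr_or, SEQ = expr_seq),
            children)
  }
  build(0L, top = TRUE)
}

# --- brute-force strict-match oracle ----------------------------------------
# Independent set comprehension over attribute-free code queries: a pathosom
# is a candidate iff every query code is among its positive subjects and no
# query code is among its excluding subjects. (Random KBs carry no synonym
# edges and no attributes, so this is the full predicate.)
oracle_match <- function(query_codes, kb) {
  hits <- character()
  for (p in kb$pathosoms) {
    subj <- vapply(p$pathophems, `[[`, character(1), "subject")
    grades <- vapply(p$pathophems, `[[`, character(1), "grade")
    pos <- subj[grades != "NOT"]
    neg <- subj[grades == "NOT"]
    if (all(query_codes %in% pos) && !any(query_codes %in% neg)) {
      hits <- c(hits, p$pathosom_id)
    }
  }
  sort(hits)
}

pv_from_codes <- function(codes) {
  do.call(patient_vector, lapply(codes, function(s) {
    el <- query_element(s)
    el$term_code <- s
    el
  }))
}

# --- small ad-hoc KBs --------------------------------------------------------

# pathosom X carries finding "c" both positively (attributed) and as a NOT
# exclusion via a synonym; lets tests observe NOT changing an outcome that
# conjunctive matching alone would not
kb_not_demo <- function() {
  terms <- list(
    atomistic_term("N1", c(en = "alpha"), 5100),
    atomistic_term("N2", c(en = "beta"), 5100),
    atomistic_term("N3", c(en = "gamma"), 5100),
    atomistic_term("N4", c(en = "gamma variant"), 5100)
  )
  psms <- list(
    pathosom("X1", "exclusion demo", pathophems = list(
      pathophem("N1", "Lead"),
      pathophem("N3", "++", attributes = list(attribute("site", "arm"))),
      pathophem("N3", "NOT")
    )),
    pathosom("X2", "plain match", pathophems = list(
      pathophem("N1", "Lead"),
      pathophem("N3", "++", attributes = list(attribute("site", "arm")))
    ))
  )
  knowledge_base(terms, psms,
                 data.frame(source = "N4", edge_type = "synonym-of",
                            target = "N3", stringsAsFactors = FALSE))
}

# four candidates sharing pathophems with known presence counts, for the
# question-selection rule
kb_narrow_demo <- function() {
  terms <- lapply(sprintf("Q%d", 1:6), function(cd)
    atomistic_term(cd, stats::setNames(paste("finding", cd), "en"), 5100))
  mk <- function(id, subjects, grades) {
    pathosom(id, paste("candidate", id),
             pathophems = mapply(pathophem, subjects, grades,
                                 SIMPLIFY = FALSE))
  }
  psms <- list(
    mk("C1", c("Q1", "Q2", "Q3"), c("Lead", "++", "+")),
    mk("C2", c("Q1", "Q2", "Q3"), c("Lead", "+", "+++")),
    mk("C3", c("Q1", "Q3", "Q4"), c("Lead", "++", "++")),
    mk("C4", c("Q1", "Q3", "Q5"), c("Lead", "++", "++"))
  )
  knowledge_base(terms, psms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
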