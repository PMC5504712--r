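# Deterministic fixtures: the worked-cases knowledge base (myelodysplasia,
# breast-nodule, Meckel and renal/fever clusters), seeded random KBs, and
# synthetic patients emitted from a source pathosom.

# run fn() under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

#' Build the worked-cases knowledge base
#'
#' A fixed, fully valid knowledge base containing four clinical clusters:
#' the myelodysplasia tree (RAEB with its coded Boolean rule, the RAEB-1/2/F
#' subsets and sibling distractors), the breast-nodule cluster (invasive
#' breast cancer plus the six lesions presenting as a non-firm mammary
#' nodule), Meckel syndrome types 1-6 (exactly types 1, 3 and 6 carry
#' polydactyly, renal cyst and encephalocele), and the renal/fever cluster
#' (eight diseases with proteinuria, hematuria and fever; 25 two-symptom
#' distractors; the MPGN subtree). Multilingual labels (e.g. Nierenzyste /
#' Nierencyste / renal cyst / renal cysts on one code) and thesaurus
#' cross-references (ICD-10-GM D46.2 and ICD-O 9983/3 on RAEB, OMIM 612284
#' on Meckel type 6) are included.
#'
#' @return A [knowledge_base()] that passes [validate_kb()] with no issues.
#' @export
build_cases_kb <- function() {
  terms <- list(
    atomistic_term("F1001", c(en = "cytopenia", de = "Zytopenie"), 5500),
    atomistic_term("F1002", c(en = "anemia", de = "Anämie"), 5500),
    atomistic_term("10209", c(en = "bone marrow", de = "Knochenmark"), 1400),
    atomistic_term("M3094", c(en = "refractory anemia"), 5500),
    atomistic_term("O812", c(en = "myeloblasts"), 5720),
    atomistic_term("10221", c(en = "peripheral blood"), 1400),
    atomistic_term("F1010", c(en = "female", de = "weiblich"), 6310),
    atomistic_term("10787Z", c(en = "nodule", en = "lump",
                               en = "palpable node",
                               de = "tastbarer Knoten"), 5400),
    atomistic_term("F1020", c(en = "polydactyly"), 5400),
    atomistic_term("M5065", c(en = "renal cyst", en = "renal cysts",
                              de = "Nierenzyste", de = "Nierencyste"), 5610),
    atomistic_term("F1021", c(en = "encephalocele"), 5400),
    atomistic_term("F1022", c(en = "microcephaly"), 5400),
    atomistic_term("F1023", c(en = "cleft palate"), 5400),
    atomistic_term("F1024", c(en = "situs inversus"), 5600),
    atomistic_term("F1025", c(en = "liver fibrosis"), 5700),
    atomistic_term("F1026", c(en = "newborn", de = "Neugeborenes"), 6320),
    atomistic_term("F1030", c(en = "proteinuria", de = "Proteinurie"), 5510),
    atomistic_term("F1031", c(en = "hematuria", de = "Hämaturie"), 5510),
    atomistic_term("F1041", c(en = "erythrocyturia"), 5510),
    atomistic_term("F1032", c(en = "fever", de = "Fieber"), 5300),
    atomistic_term("F1033", c(en = "edema"), 5400),
    atomistic_term("F1034", c(en = "hypertension"), 5300),
    atomistic_term("F1035", c(en = "oliguria"), 5100),
    atomistic_term("F1036", c(en = "flank pain"), 5100),
    atomistic_term("F1037", c(en = "rash"), 5400),
    atomistic_term("F1038", c(en = "arthralgia"), 5100),
    atomistic_term("F1039", c(en = "weight loss"), 5100),
    atomistic_term("F1040", c(en = "nausea"), 5100),
    atomistic_term("F1050", c(en = "finger", de = "Finger"), 1400),
    atomistic_term("F1051", c(en = "hand", de = "Hand"), 1400),
    atomistic_term("F1052", c(en = "joint swelling"), 5400),
    atomistic_term("F1053", c(en = "consistency"), 1100)
  )

  hypercellular <- attribute("cellularity", "hypercellular")
  normocellular <- attribute("cellularity", "normocellular")
  core_raeb <- function() list(
    pathophem("F1001", "Lead"),
    pathophem("F1002", "Lead"),
    pathophem("10209", "+++", attributes = list(hypercellular))
  )
  adult_female <- function(lo = 35, hi = 90) list(
    pathophem("F1010", "Lead",
              attributes = list(attribute("age", c(lo, hi), unit = "years")))
  )
  mam_nodule <- function(grade = "++", firm = FALSE) {
    attrs <- list(attribute("site", "mamma"))
    if (firm) attrs <- c(list(attribute("intensity", "firm")), attrs)
    pathophem("10787Z", grade, attributes = attrs)
  }

  breast_distractor <- function(id, name) {
    pathosom(id, name,
             pathophems = c(adult_female(15, 90), list(mam_nodule("++"))))
  }

  pool <- c("F1033", "F1034", "F1035", "F1036",
            "F1037", "F1038", "F1039", "F1040")
  fever_psm <- function(id, name, extra) {
    pathosom(id, name, pathophems = list(
      pathophem("F1030", "+++"),
      pathophem("F1031", "++"),
      pathophem("F1032", "++"),
      pathophem(extra, "+")
    ))
  }
  distractor <- function(i) {
    phs <- list(pathophem("F1030", "++"), pathophem("F1031", "++"),
                pathophem(pool[(i - 1L) %% length(pool) + 1L], "+"))
    if (i == 1L) phs <- c(phs, list(pathophem("F1032", "NOT")))
    pathosom(sprintf("F23%02d", 20L + i),
             sprintf("proteinuria-hematuria distractor %02d", i),
             pathophems = phs)
  }

  meckel <- function(id, name, subjects, grades, xrefs = list()) {
    pathosom(id, name, parent = "F2200",
             pathophems = c(
               mapply(function(s, g) pathophem(s, g), subjects, grades,
                      SIMPLIFY = FALSE),
               list(pathophem("F1026", "Lead"))),
             xrefs = xrefs)
  }

  pathosoms <- c(list(
    # --- myelodysplasia tree -------------------------------------------
    pathosom("F2000", "myelodysplasia",
             pathophems = list(pathophem("F1001", "Lead"),
                               pathophem("F1002", "++")),
             children = c("M3501", "F2005", "F2006")),
    pathosom("M3501", "RAEB (refractory anemia with excess of blasts)",
             pathophems = c(core_raeb(),
                            list(pathophem("M3094", "Lead"),
                                 pathophem("O812", "++"))),
             rule = "M3094|; (O812| & 10209|: 5..20%) | (10221 T| &10209 T|: 2..20%)",
             parent = "F2000", children = c("M3502", "M3503", "M3504"),
             xrefs = list(thesaurus_ref("ICD-10-GM", "D46.2"),
                          thesaurus_ref("ICD-O", "9983/3"))),
    pathosom("M3502", "RAEB-1", parent = "M3501",
             pathophems = c(core_raeb(), list(pathophem("O812", "++")))),
    pathosom("M3503", "RAEB-2", parent = "M3501",
             pathophems = c(core_raeb(), list(pathophem("O812", "+++")))),
    pathosom("M3504", "RAEB-F", parent = "M3501",
             pathophems = c(core_raeb(), list(pathophem("O812", "++")))),
    pathosom("F2005", "refractory cytopenia with multilineage dysplasia",
             parent = "F2000",
             pathophems = list(pathophem("F1001", "Lead"),
                               pathophem("F1002", "++"),
                               pathophem("10209", "++",
                                         attributes = list(normocellular)))),
    pathosom("F2006", "refractory anemia with ring sideroblasts",
             parent = "F2000",
             pathophems = c(list(pathophem("F1002", "Lead"),
                                 pathophem("M3094", "Lead"),
                                 pathophem("10209", "++",
                                           attributes = list(hypercellular))))),
    # --- breast-nodule cluster -----------------------------------------
    pathosom("F2100", "invasive breast cancer",
             pathophems = c(adult_female(35, 90),
                            list(mam_nodule("+++", firm = TRUE)))),
    breast_distractor("F2101", "angiosarcoma of breast"),
    breast_distractor("F2102", "secretory breast cancer"),
    breast_distractor("F2103", "benign breast tumor"),
    breast_distractor("F2104", "pseudoangiomatoid stroma hyperplasia"),
    breast_distractor("F2105", "fibroadenoma"),
    breast_distractor("F2106", "breast papilloma"),
    # --- Meckel syndrome tree ------------------------------------------
    pathosom("F2200", "Meckel syndrome",
             pathophems = list(pathophem("M5065", "Lead"),
                               pathophem("F1021", "++"),
                               pathophem("F1026", "Lead")),
             children = sprintf("F22%02d", 1:6)),
    meckel("F2201", "Meckel syndrome type 1",
           c("F1020", "M5065", "F1021", "F1025"),
           c("+++", "Lead", "+++", "++")),
    meckel("F2202", "Meckel syndrome type 2",
           c("M5065", "F1021", "F1023"), c("Lead", "++", "++")),
    meckel("F2203", "Meckel syndrome type 3",
           c("F1020", "M5065", "F1021", "F1022"),
           c("++", "Lead", "++", "+")),
    meckel("F2204", "Meckel syndrome type 4",
           c("M5065", "F1022", "F1023"), c("Lead", "++", "++")),
    meckel("F2205", "Meckel syndrome type 5",
           c("M5065", "F1024", "F1020"), c("Lead", "++", "++")),
    meckel("F2206", "Meckel syndrome type 6",
           c("F1020", "M5065", "F1021"), c("+++", "Lead", "++"),
           xrefs = list(thesaurus_ref("OMIM", "612284"))),
    # --- renal / fever cluster -----------------------------------------
    fever_psm("F2301", "cryoglobulinemia with vasculitis", "F1037"),
    fever_psm("F2302", "periarteriitis nodosa", "F1038"),
    fever_psm("F2303", "microscopic polyangiitis", "F1037"),
    fever_psm("F2304", "hanta virus infection", "F1036"),
    fever_psm("F2305", "hemorrhagic fever with renal syndrome", "F1036"),
    fever_psm("F2306", "emphysematous pyelonephritis", "F1035"),
    fever_psm("F2307", "infective glomerulonephritis", "F1033"),
    fever_psm("F2308", "acute interstitial nephritis", "F1037"),
    pathosom("F2310", "membranoproliferative glomerulonephritis (MPGN)",
             pathophems = list(pathophem("F1030", "Lead"),
                               pathophem("F1031", "+++")),
             children = c("F2311", "F2312", "F2313"),
             xrefs = list(thesaurus_ref("ICD-10-GM", "N05.5"))),
    pathosom("F2311", "MPGN type I", parent = "F2310",
             pathophems = list(pathophem("F1030", "Lead"),
                               pathophem("F1031", "+++"))),
    pathosom("F2312", "MPGN type II", parent = "F2310",
             pathophems = list(pathophem("F1030", "Lead"),
                               pathophem("F1031", "+++"))),
    pathosom("F2313", "MPGN type III", parent = "F2310",
             pathophems = list(pathophem("F1030", "Lead"),
                               pathophem("F1031", "+++"))),
    # --- anatomy demo ---------------------------------------------------
    pathosom("F2400", "hand arthritis",
             pathophems = list(pathophem("F1051", "Lead"),
                               pathophem("F1052", "++")))
  ), lapply(1:25, distractor))

  edges <- data.frame(
    source = c("F1041", "F1050", "M3094", "10787Z"),
    edge_type = c("synonym-of", "is-part-of", "is-a", "has-attribute-of"),
    target = c("F1031", "F1051", "F1002", "F1053"),
    stringsAsFactors = FALSE
  )
  knowledge_base(terms, pathosoms, edges)
}

#' Specification for a random knowledge base
#'
#' @param seed Integer RNG seed.
#' @param n_pathosoms,n_terms Positive counts.
#' @param pathophems_per_pathosom Length-2 integer range `c(lo, hi)`.
#' @param grade_probs Named probabilities over the five positive grade
#'   symbols; must sum to 1. The first pathophem of every pathosom is always
#'   Lead-graded (every prototype has a lead finding); the remainder are
#'   drawn from this distribution.
#' @param not_fraction Fraction of pathosoms carrying one excluding (NOT)
#'   pathophem.
#' @param tree_depth Maximum depth of the pathosom subset tree.
#' @export
fixture_spec <- function(seed, n_pathosoms = 20, n_terms = 60,
                         pathophems_per_pathosom = c(4, 8),
                         grade_probs = c("Lead" = 0.15, "+++" = 0.25,
                                         "++" = 0.30, "+" = 0.20,
                                         "(+)" = 0.10),
                         not_fraction = 0.2, tree_depth = 2) {
  stopifnot(length(seed) == 1, n_pathosoms >= 1, n_terms >= 1,
            length(pathophems_per_pathosom) == 2,
            pathophems_per_pathosom[1] >= 1,
            pathophems_per_pathosom[1] <= pathophems_per_pathosom[2],
            not_fraction >= 0, not_fraction <= 1, tree_depth >= 1)
  if (!setequal(names(grade_probs), setdiff(grade_symbols(), "NOT"))) {
    stop("grade_probs must name exactly the five positive grades",
         call. = FALSE)
  }
  if (abs(sum(grade_probs) - 1) > 1e-8) {
    stop("grade probabilities must sum to 1", call. = FALSE)
  }
  if (pathophems_per_pathosom[2] + 1 > n_terms) {
    stop("infeasible spec: more pathophems per pathosom than available terms",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_pathosoms = as.integer(n_pathosoms),
                 n_terms = as.integer(n_terms),
                 pathophems_per_pathosom = as.integer(pathophems_per_pathosom),
                 grade_probs = grade_probs,
                 not_fraction = not_fraction,
                 tree_depth = as.integer(tree_depth)),
            class = "fixture_spec")
}

#' Generate a seeded random knowledge base
#'
#' Deterministic given the spec's seed: the same spec always yields a
#' field-identical (and, via [save_kb()], byte-identical) knowledge base.
#' Hierarchical `is-a` edges among terms always point from a
#' higher-numbered to a lower-numbered code, so the network is acyclic by
#' construction.
#'
#' @param spec A [fixture_spec()].
#' @return A valid [knowledge_base()].
#' @export
generate_random_kb <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, function() {
    tcodes <- sprintf("R%04d", seq_len(spec$n_terms))
    classes <- class_table()$code
    terms <- lapply(seq_len(spec$n_terms), function(i) {
      atomistic_term(tcodes[i], c(en = sprintf("finding %04d", i)),
                     sample(classes, 1))
    })
    pcodes <- sprintf("D%04d", seq_len(spec$n_pathosoms))
    depth <- rep(1L, spec$n_pathosoms)
    parent <- rep(NA_character_, spec$n_pathosoms)
    for (i in seq_len(spec$n_pathosoms)[-1]) {
      cand <- which(depth[seq_len(i - 1L)] < spec$tree_depth)
      if (length(cand) && stats::runif(1) < 0.3) {
        j <- cand[sample.int(length(cand), 1)]
        parent[i] <- pcodes[j]
        depth[i] <- depth[j] + 1L
      }
    }
    grades <- names(spec$grade_probs)
    lo <- spec$pathophems_per_pathosom[1]
    hi <- spec$pathophems_per_pathosom[2]
    pathosoms <- lapply(seq_len(spec$n_pathosoms), function(i) {
      k <- sample(seq(lo, hi), 1)
      subj <- sample(tcodes, k)
      g <- c("Lead",
             if (k > 1) sample(grades, k - 1, replace = TRUE,
                               prob = spec$grade_probs))
      phs <- mapply(function(s, gr) pathophem(s, gr), subj, g,
                    SIMPLIFY = FALSE)
      if (stats::runif(1) < spec$not_fraction) {
        not_subj <- sample(setdiff(tcodes, subj), 1)
        phs <- c(phs, list(pathophem(not_subj, "NOT")))
      }
      pathosom(pcodes[i], sprintf("disease %04d", i),
               pathophems = unname(phs), parent =
                 if (is.na(parent[i])) NULL else parent[i],
               children = pcodes[which(parent == pcodes[i])])
    })
    n_edges <- max(1L, spec$n_terms %/% 3L)
    src_i <- sample(seq_len(spec$n_terms)[-1], n_edges,
                    replace = n_edges > spec$n_terms - 1L)
    edges <- data.frame(
      source = tcodes[src_i],
      edge_type = "is-a",
      target = vapply(src_i, function(j) tcodes[sample.int(j - 1L, 1)],
                      character(1)),
      stringsAsFactors = FALSE)
    knowledge_base(terms, pathosoms, unique(edges))
  })
}

#' Generate a synthetic patient from a source pathosom
#'
#' Each non-excluding pathophem of the source pathosom is emitted
#' independently with probability `sensitivity * grade_weight(grade)` (an
#' explicit stored probability wins over the grade); the emitted set is
#' truncated to the five highest-grade findings and returned as an
#' attribute-free patient vector. Deterministic given the seed.
#'
#' @param pathosom_id Source pathosom id in `kb`.
#' @param kb A [knowledge_base()].
#' @param sensitivity Emission scaling in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_patient` with fields `source`,
#'   `vector` (a [patient_vector()]) and `sensitivity`. Emitting no finding
#'   at all is an error.
#' @export
generate_patient <- function(pathosom_id, kb, sensitivity, seed) {
  stopifnot(sensitivity >= 0, sensitivity <= 1)
  psm <- kb$pathosoms[[pathosom_id]]
  if (is.null(psm)) stop("unknown pathosom id: ", pathosom_id, call. = FALSE)
  phs <- Filter(function(ph) ph$grade != "NOT", psm$pathophems)
  if (!length(phs)) {
    stop("pathosom ", pathosom_id, " has no non-NOT pathophems",
         call. = FALSE)
  }
  .with_seed(seed, function() {
    w <- vapply(phs, .ph_weight, numeric(1))
    emit <- stats::runif(length(phs)) < sensitivity * w
    if (!any(emit)) {
      stop("empty emission: no pathophem of ", pathosom_id,
           " was emitted at sensitivity ", sensitivity, call. = FALSE)
    }
    sel <- which(emit)
    sel <- sel[order(-w[sel], sel)]
    subj <- unique(vapply(phs[sel], `[[`, character(1), "subject"))
    subj <- utils::head(subj, 5L)
    elements <- lapply(subj, function(s) {
      el <- query_element(s)
      el$term_code <- s
      el
    })
    structure(list(source = pathosom_id,
                   vector = structure(elements, class = "patient_vector"),
                   sensitivity = sensitivity),
              class = "synthetic_patient")
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> from %s (sensitivity %g):\n",
              x$source, x$sensitivity))
  print(x$vector)
  invisible(x)
}
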