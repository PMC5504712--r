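cases_kb <- build_cases_kb()

pv_case1 <- function() patient_vector(
  "cytopenia", "anemia",
  query_element("bone marrow",
                list(attribute("cellularity", "hypercellular"))))
pv_case2 <- function() patient_vector(
  query_element("female", list(attribute("age", 55, unit = "years"))),
  query_element("nodule", list(attribute("intensity", "firm"))),
  query_element("nodule", list(attribute("site", "mamma"))))

test_that("verification resolves surfaces and reports issues", {
  v <- verify_vector(pv_case1(), cases_kb)
  expect_true(v$ok)
  expect_identical(
    vapply(v$vector, `[[`, character(1), "term_code"),
    c("F1001", "F1002", "10209"))

  v2 <- verify_vector(patient_vector("frobnitz", "anemia"), cases_kb)
  expect_false(v2$ok)
  expect_identical(v2$issues$issue, "unresolvable")

  expect_error(verify_vector(patient_vector("frobnitz"), cases_kb),
               "empty query")
})

test_that("the myelodysplasia query narrows to a single rolled-up diagnosis", {
  strict <- match_strict(pv_case1(), cases_kb)
  expect_setequal(strict, c("M3501", "M3502", "M3503", "M3504"))
  res <- run_query(pv_case1(), cases_kb)
  expect_length(res, 1)
  expect_identical(res[[1]]$pathosom_id, "M3501")
  # an incompatible attribute (normocellular marrow) blocks the distractor
  expect_false("F2005" %in% strict)
})

test_that("attribute compatibility: numeric in range, category equal, ordinal at least", {
  terms <- list(atomistic_term("T1", c(en = "finding one"), 5100))
  psm <- pathosom("P1", "demo", pathophems = list(
    pathophem("T1", "++", attributes = list(
      attribute("age", c(10, 20), unit = "years"),
      attribute("intensity", "strong", kind = "ordinal",
                scale = c("weak", "moderate", "strong"))))))
  kb <- knowledge_base(terms, list(psm))
  q <- function(...) patient_vector(query_element("T1", list(...)))
  expect_identical(match_strict(q(attribute("age", 15, unit = "years")), kb),
                   "P1")
  expect_identical(match_strict(q(attribute("age", 20, unit = "years")), kb),
                   character())   # open upper bound
  expect_identical(match_strict(q(attribute("age", 15, unit = "months")), kb),
                   character())   # unit mismatch
  expect_identical(
    match_strict(q(attribute("intensity", "strong", kind = "ordinal",
                             scale = c("weak", "moderate", "strong"))), kb),
    "P1")
  expect_identical(
    match_strict(q(attribute("intensity", "weak", kind = "ordinal",
                             scale = c("weak", "moderate", "strong"))), kb),
    character())   # below the pathophem's minimum level
  # attribute with no counterpart: rejected strictly, accepted relaxed
  expect_identical(match_strict(q(attribute("color", "red")), kb), character())
  expect_identical(
    match_strict(q(attribute("color", "red")), kb,
                 query_config(mode = "relaxed")), "P1")
})

test_that("a NOT pathophem excludes even when everything else matches", {
  kb <- kb_not_demo()
  pv <- pv_from_codes(c("N1", "N3"))
  # X2 (no exclusion) matches; X1 is identical except for the NOT -> absent
  expect_identical(match_strict(pv, kb), "X2")
  # the exclusion also acts through synonym closure
  pv_syn <- pv_from_codes(c("N1", "N4"))
  expect_identical(match_strict(pv_syn, kb), "X2")
})

test_that("scores are grade-weighted means with deterministic tie-breaks", {
  terms <- lapply(sprintf("T%d", 1:3), function(cd)
    atomistic_term(cd, stats::setNames(paste("f", cd), "en"), 5100))
  mk <- function(id, grades) pathosom(id, id, pathophems = mapply(
    pathophem, sprintf("T%d", 1:3), grades, SIMPLIFY = FALSE))
  kb <- knowledge_base(terms, list(
    mk("P1", c("Lead", "Lead", "Lead")),
    mk("P2", c("+++", "+++", "+++")),
    mk("P3", c("+", "+", "+"))))
  pv <- pv_from_codes(c("T1", "T2", "T3"))
  res <- rank_candidates(match_strict(pv, kb), pv, kb)
  ids <- vapply(res, `[[`, character(1), "pathosom_id")
  expect_identical(ids, c("P1", "P2", "P3"))
  expect_identical(res[[1]]$score, 1)          # three Lead matches / 3
  expect_equal(res[[2]]$score, 0.745)
  expect_identical(rank_candidates(character(), pv, kb),
                   structure(list(), class = "match_results"))
  # an explicit probability overrides the grade weight
  kb2 <- knowledge_base(terms, list(
    mk("P1", c("+++", "+++", "+++")),
    pathosom("P2", "P2", pathophems = mapply(
      pathophem, sprintf("T%d", 1:3), list("+++", "+++", "+++"),
      MoreArgs = list(prob = 0.95), SIMPLIFY = FALSE))))
  res2 <- rank_candidates(match_strict(pv, kb2), pv, kb2)
  expect_identical(res2[[1]]$pathosom_id, "P2")
})

test_that("roll-up keeps the most general equal-evidence representative", {
  # equal evidence: the whole RAEB subtree collapses to RAEB
  pv <- pv_case1()
  res <- roll_up(rank_candidates(match_strict(pv, cases_kb), pv, cases_kb),
                 cases_kb)
  expect_identical(vapply(res, `[[`, character(1), "pathosom_id"), "M3501")

  # different matched sets: parent and child both retained
  terms <- list(atomistic_term("T1", c(en = "fa"), 5100),
                atomistic_term("T2", c(en = "fb"), 5100))
  kb <- knowledge_base(terms, list(
    pathosom("P1", "parent", pathophems = list(pathophem("T1", "Lead")),
             children = "P2"),
    pathosom("P2", "child", parent = "P1",
             pathophems = list(pathophem("T1", "Lead"),
                               pathophem("T2", "++")))))
  pv2 <- pv_from_codes(c("T1", "T2"))
  cand <- match_strict(pv2, kb)
  expect_identical(cand, "P2")  # parent lacks T2
  # single-element query: both match equally -> child rolled away
  pv1 <- pv_from_codes("T1")
  res1 <- roll_up(rank_candidates(match_strict(pv1, kb), pv1, kb), kb)
  expect_identical(vapply(res1, `[[`, character(1), "pathosom_id"), "P1")
  # tree-free results: identity
  res_flat <- rank_candidates(match_strict(pv2, kb), pv2, kb)
  expect_identical(roll_up(res_flat, kb), res_flat)
})

test_that("broadening drops the most specific attribute first (breast cluster)", {
  strict <- match_strict(pv_case2(), cases_kb)
  expect_identical(strict, "F2100")
  b <- broaden(pv_case2(), cases_kb, force = TRUE)
  extra <- setdiff(b$candidates, strict)
  expect_length(extra, 6)
  expect_setequal(
    vapply(extra, function(id) cases_kb$pathosoms[[id]]$name, character(1)),
    c("angiosarcoma of breast", "secretory breast cancer",
      "benign breast tumor", "pseudoangiomatoid stroma hyperplasia",
      "fibroadenoma", "breast papilloma"))
  expect_match(b$trace[1], "intensity=firm")
  # relaxed matches rank below the exact one
  res <- rank_candidates(b$candidates, b$vector, cases_kb)
  expect_identical(res[[1]]$pathosom_id, "F2100")
  expect_true(all(vapply(res[-1], `[[`, numeric(1), "score") <
                    res[[1]]$score))
})

test_that("broadening generalizes terms when attributes do not help", {
  pv <- patient_vector("finger")
  expect_identical(match_strict(pv, cases_kb), character())
  b <- broaden(pv, cases_kb)
  expect_identical(b$candidates, "F2400")
  expect_true(any(grepl("generalize", b$trace)))
  res <- rank_candidates(b$candidates, b$vector, cases_kb)
  expect_identical(res[[1]]$matched$level, "generalized")

  # nothing to do when the strict result already suffices
  b1 <- broaden(pv_case1(), cases_kb)
  expect_identical(b1$trace, character())
  expect_identical(b1$candidates, match_strict(pv_case1(), cases_kb))
})

test_that("broadened candidate sets are supersets of the strict set", {
  set.seed(55)
  for (rep in 1:10) {
    kb <- generate_random_kb(fixture_spec(seed = 7000 + rep,
                                          n_pathosoms = 12, n_terms = 20))
    codes <- sample(names(kb$lexicon), sample(1:3, 1))
    pv <- pv_from_codes(codes)
    strict <- match_strict(pv, kb)
    b <- broaden(pv, kb, force = TRUE)
    expect_true(all(strict %in% b$candidates))
  }
})

test_that("question selection picks the most even split, then higher grades", {
  kb <- kb_narrow_demo()
  pv <- pv_from_codes("Q1")
  # Q2 occurs in 2 of 4 candidates, Q3 in 4 of 4: ask about Q2
  sug <- narrow_suggest(c("C1", "C2", "C3", "C4"), pv, kb)
  expect_identical(sug$term_code, "Q2")
  # two candidates sharing Q2 and Q3 equally: the higher-graded Q3 wins
  sug2 <- narrow_suggest(c("C1", "C2"), pv, kb)
  expect_identical(sug2$term_code, "Q3")
  expect_error(narrow_suggest("C1", pv, kb), "nothing to ask")
})

test_that("dialogue terminates immediately on a unique diagnosis", {
  out <- dialogue(pv_case1(), cases_kb)
  expect_identical(vapply(out$results, `[[`, character(1), "pathosom_id"),
                   "M3501")
  expect_identical(nrow(out$transcript), 0L)
})

test_that("dialogue with only NA answers still terminates with a ranking", {
  pv <- patient_vector("proteinuria", "hematuria")
  out <- dialogue(pv, cases_kb, answer_provider = function(sug) NA)
  expect_true(length(out$results) > 0)
  expect_true(all(out$transcript$action == "ask"))
  expect_true(all(is.na(out$transcript$answer) |
                    out$transcript$answer == "NA"))
})

test_that("answering the fever question replays the three-term query", {
  pv <- patient_vector("proteinuria", "hematuria")
  out <- dialogue(pv, cases_kb, answer_provider = function(sug) {
    if (sug$term_code == "F1032") TRUE else NA
  })
  direct <- run_query(patient_vector("proteinuria", "hematuria", "fever"),
                      cases_kb)
  expect_identical(
    vapply(out$results, `[[`, character(1), "pathosom_id"),
    vapply(direct, `[[`, character(1), "pathosom_id"))
  expect_true("F1032" %in% out$transcript$detail)
})

test_that("a FALSE answer only excludes candidates requiring the finding at Lead", {
  terms <- lapply(sprintf("T%d", 1:4), function(cd)
    atomistic_term(cd, stats::setNames(paste("f", cd), "en"), 5100))
  mk <- function(id, subjects, grades) pathosom(
    id, id, pathophems = mapply(pathophem, subjects, grades,
                                SIMPLIFY = FALSE))
  # 12 candidates so the dialogue must narrow; T2 is Lead in half of them
  psms <- lapply(1:12, function(i) {
    mk(sprintf("P%02d", i), c("T1", "T2"),
       c("Lead", if (i <= 6) "Lead" else "++"))
  })
  kb <- knowledge_base(terms, psms)
  pv <- pv_from_codes("T1")
  out <- dialogue(pv, kb, query_config(max_results = 10),
                  answer_provider = function(sug)
                    if (sug$term_code == "T2") FALSE else NA)
  ids <- vapply(out$results, `[[`, character(1), "pathosom_id")
  expect_setequal(ids, sprintf("P%02d", 7:12))
})

test_that("the engine is deterministic", {
  pv <- patient_vector("proteinuria", "hematuria")
  run <- function() dialogue(pv, cases_kb, answer_provider = function(sug) {
    if (sug$term_code == "F1032") TRUE else NA
  })
  expect_identical(run(), run())
  expect_identical(run_query(pv_case2(), cases_kb),
                   run_query(pv_case2(), cases_kb))
})

test_that("adding a query element never enlarges the strict result set", {
  set.seed(66)
  for (rep in 1:15) {
    kb <- generate_random_kb(fixture_spec(seed = 8000 + rep,
                                          n_pathosoms = 15, n_terms = 25))
    codes <- sample(names(kb$lexicon), 4)
    for (k in 1:3) {
      base <- match_strict(pv_from_codes(codes[seq_len(k)]), kb)
      ext <- match_strict(pv_from_codes(codes[seq_len(k + 1)]), kb)
      expect_true(all(ext %in% base))
    }
  }
})

test_that("strict matching equals the brute-force comprehension oracle", {
  set.seed(88)
  for (rep in 1:12) {
    kb <- generate_random_kb(fixture_spec(seed = 9000 + rep,
                                          n_pathosoms = 20, n_terms = 15,
                                          pathophems_per_pathosom = c(3, 6)))
    for (q in 1:5) {
      codes <- sample(names(kb$lexicon), sample(1:5, 1))
      expect_identical(match_strict(pv_from_codes(codes), kb),
                       oracle_match(codes, kb))
    }
  }
})

test_that("case evaluation reports identification rate and lower median", {
  kb <- cases_kb
  cases <- list(
    list(vector = patient_vector("polydactyly", "renal cyst",
                                 "encephalocele"),
         expected = "F2203"),
    list(vector = pv_case1(), expected = "M3502"),   # rolled up to M3501
    list(vector = patient_vector("proteinuria", "hematuria", "fever"),
         expected = "F2301"),
    list(vector = patient_vector("cytopenia", "fever"),
         expected = "F2301"))  # no pathosom carries both -> miss
  ev <- evaluate_cases(cases, kb)
  expect_identical(ev$cases$n_proposals[1], 3L)
  expect_identical(ev$cases$identified, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ev$identification_rate, 0.75)
  # proposal counts 3, 1, 8, 0 -> sorted 0 1 3 8 -> lower median 1
  expect_identical(ev$median_proposal_count, 1L)
  ev1 <- evaluate_cases(cases[1], kb)
  expect_identical(ev1$median_proposal_count, 3L)
})
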