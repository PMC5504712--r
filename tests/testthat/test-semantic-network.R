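test_that("label resolution is case- and diacritic-insensitive", {
  kb <- build_cases_kb()
  for (s in c("renal cyst", "renal cysts", "Nierenzyste", "Nierencyste",
              "NIERENZYSTE", "nierencyste")) {
    res <- resolve_term(s, kb)
    expect_identical(res$term_code[1], "M5065")
    expect_identical(res$match_kind[1], "exact-label")
  }
  # diacritic folding: the umlaut label is reachable from its ASCII form
  res <- resolve_term("anamie", kb)
  expect_identical(res$term_code[res$match_kind == "exact-label"], "F1002")
  # language restriction: a German label is no exact match in English
  res_en <- resolve_term("Nierenzyste", kb, language = "en")
  expect_false("exact-label" %in% res_en$match_kind)
})

test_that("synonym-of edges surface as synonym matches", {
  kb <- build_cases_kb()
  res <- resolve_term("erythrocyturia", kb)
  expect_identical(res$match_kind[res$term_code == "F1041"], "exact-label")
  expect_identical(res$match_kind[res$term_code == "F1031"], "synonym")
  # exact matches precede synonyms which precede (absent) fuzzy rows
  expect_identical(res$match_kind, c("exact-label", "synonym"))
})

test_that("fuzzy suggestions appear only without exact matches", {
  kb <- build_cases_kb()
  res <- resolve_term("renal zyst", kb)
  expect_true(all(res$match_kind == "fuzzy-suggestion"))
  expect_identical(res$term_code[1], "M5065")
  expect_true(all(res$similarity >= 0.8))
  # garbage resolves to an empty result, not an error
  expect_identical(nrow(resolve_term("qqqqqqqqqqq", kb)), 0L)
})

test_that("every fixture label resolves back to its own term exactly", {
  kb <- build_cases_kb()
  for (t in kb$lexicon) {
    for (i in seq_len(nrow(t$labels))) {
      res <- resolve_term(t$labels$surface[i], kb)
      exact <- res$term_code[res$match_kind == "exact-label"]
      expect_true(t$term_code %in% exact)
    }
  }
})

test_that("generalization walks broader terms breadth-first", {
  net <- semantic_net(data.frame(
    source = c("A1", "B1"), edge_type = "is-a", target = c("B1", "C1"),
    stringsAsFactors = FALSE))
  # BFS oracle on the 3-node chain: one hop gives B1, two give B1 then C1
  expect_identical(generalize("A1", net, 1), "B1")
  expect_identical(generalize("A1", net, 2), c("B1", "C1"))
  expect_identical(generalize("C1", net, 2), character())
  expect_error(generalize("Z1", net, 1), "unknown node")

  kb <- build_cases_kb()
  expect_identical(generalize("F1050", kb$net, 1), "F1051")
})

test_that("generalize never returns the start term nor exceeds max_steps", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    codes <- sprintf("G%d", seq_len(n))
    # edges from higher to lower index only: acyclic by construction
    src <- sample(2:n, n, replace = TRUE)
    tgt <- vapply(src, function(j) sample(seq_len(j - 1L), 1), integer(1))
    net <- semantic_net(data.frame(
      source = codes[src],
      edge_type = sample(c("is-a", "is-part-of", "is-class-of"), n,
                         replace = TRUE),
      target = codes[tgt], stringsAsFactors = FALSE), nodes = codes)
    for (start in codes) {
      for (k in 1:3) {
        out <- generalize(start, net, k)
        expect_false(start %in% out)
        if (length(out)) {
          g <- net$edges
          # re-derive hop distances with a plain BFS oracle
          dist <- stats::setNames(rep(Inf, length(net$nodes)), net$nodes)
          dist[start] <- 0
          frontier <- start
          step <- 0
          while (length(frontier) && step < k) {
            step <- step + 1
            nxt <- unique(g$target[g$source %in% frontier])
            nxt <- nxt[dist[nxt] == Inf]
            dist[nxt] <- step
            frontier <- nxt
          }
          expect_true(all(dist[out] <= k))
          expect_setequal(out, names(dist)[is.finite(dist) & dist > 0])
        }
      }
    }
  }
})

test_that("has-attribute-of edges are not followed by generalization", {
  kb <- build_cases_kb()
  expect_false("F1053" %in% generalize("10787Z", kb$net, 3))
})

test_that("acyclicity check reports real cycles and exempts synonyms", {
  kb <- build_cases_kb()
  expect_identical(check_acyclic(kb$net), list())

  cyc_net <- semantic_net(data.frame(
    source = c("A1", "B1"), edge_type = "is-a", target = c("B1", "A1"),
    stringsAsFactors = FALSE))
  cycles <- check_acyclic(cyc_net)
  expect_length(cycles, 1)
  cy <- cycles[[1]]
  expect_identical(cy[1], cy[length(cy)])
  expect_setequal(unique(cy), c("A1", "B1"))

  syn_net <- semantic_net(data.frame(
    source = c("A1", "B1"), edge_type = "synonym-of", target = c("B1", "A1"),
    stringsAsFactors = FALSE))
  expect_identical(check_acyclic(syn_net), list())
  expect_error(semantic_net(data.frame(
    source = "A1", edge_type = "is-a", target = "A1",
    stringsAsFactors = FALSE)), "self-loop")
  expect_error(semantic_net(data.frame(
    source = "A1", edge_type = "related-to", target = "B1",
    stringsAsFactors = FALSE)), "unknown edge type")
})

test_that("edge lists round-trip through TSV", {
  kb <- build_cases_kb()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(kb$net, path)
  net2 <- read_edges_tsv(path)
  expect_identical(net2$edges, kb$net$edges)
})
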