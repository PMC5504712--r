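Package: pathosom
Title: Prototypic Disease Vectors and a Linguistic Diagnostic Matching Game
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A formalized medical-knowledge representation in which diseases
    are prototypic vectors ("pathosoms") of graded, attributed findings
    ("pathophems") coded against harmonized thesauri, together with the
    diagnostic "linguistic game": a deterministic dialogue engine that
    verifies a patient vector of up to five attributed terms against the
    knowledge base, ranks candidate diagnoses, rolls equal-evidence results
    up a disease tree, narrows large candidate sets by asking the most
    discriminating question, and broadens empty ones through a typed
    semantic network (is-a, is-part-of, is-class-of). Includes a parser and
    three-valued (Kleene) evaluator for the coded Boolean rule language
    attached to disease prototypes, JSON/TSV knowledge-base serialization,
    and deterministic fixture generators (worked clinical cases, seeded
    random knowledge bases, synthetic patients).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
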