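---
title: "Disease prototypes and the linguistic diagnostic game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease prototypes and the linguistic diagnostic game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathosom)
```

## The knowledge model

`pathosom` represents a disease as a *prototype vector* rather than a rule
set or a probabilistic model. The building blocks are:

* **Atomistic term** — a stem-word concept with a singular internal code
  (pattern: optional uppercase letter, digits, optional flag letter, e.g.
  `M3094`, `O812`, `10209`, `10787Z`), multilingual labels (German, English,
  Latin) and cross-references into external thesauri. Cross-references are
  opaque strings: the package never ingests ICD-10 or SNOMED releases.
* **Pathophem** — one finding inside a disease description: a term plus at
  most three attributes (cardinal categories, ordinal levels on a declared
  scale, or numbers/half-open intervals with units) and an occurrence grade.
* **Pathosom** — the disease prototype: a vector of pathophems, an optional
  coded Boolean rule, and a position in a subset tree (`is-element-of` /
  `has-element`, with `has-variant` links for variants).
* **Semantic network** — a typed directed graph over codes supplying
  synonymy, generalization and classification context. The subgraph of
  hierarchical types must be acyclic; `check_acyclic()` enforces this so
  query broadening always terminates.

### Occurrence grades

The grade symbols map to probability intervals: `Lead` = [1, 1] (always
present), `+++` = [0.5, 0.99], `++` = [0.1, 0.49], `+` = [0.01, 0.09],
`(+)` = [0, 0.01), and `NOT` marks an excluding finding with no interval.
Two deliberate choices:

* The printed bounds leave *gaps* (nothing between 0.09 and 0.1, or between
  0.49 and 0.5). The mapping reproduces the bounds verbatim instead of
  closing the gaps, and an explicit numeric occurrence probability stored on
  a pathophem is rejected if it falls into a gap. Whether `(+)` includes
  exactly 0 is not specified anywhere; this implementation includes it.
* For ranking, a grade is scalarized to its interval midpoint
  (`grade_weight()`: 1, 0.745, 0.295, 0.05, 0.005); an explicit numeric
  probability, when present, wins over the symbol. Midpoints are the least
  committal scalarization and keep the weight function strictly increasing
  along the grade order.

## The coded rule language

A pathosom may carry a machine-checkable admission rule, e.g. for RAEB:

```
M3094|; (O812| & 10209|: 5..20%) | (10221 T| &10209 T|: 2..20%)
```

Grammar: `;` separates top-level clauses (all must hold), `&` binds tighter
than the OR `|`, parentheses group, and an atom is a term code (plus an
optional one-letter flag) *terminated by* `|`, optionally followed by `:`
and a constraint. Design decisions forced by the sparse surface syntax:

* **`|` ambiguity.** A `|` immediately following a code token (plus optional
  flag) is the atom terminator; any other `|` is the OR operator. This is
  the only reading consistent with the expression shape above.
* **Ranges are `[lo, hi)`.** `5..20%` admits 5 and excludes 20 — a
  compromise between prose that says "> 5% … < 20%" and the classification
  convention "5–19%"; recorded as an open question.
* **The `T` flag is opaque.** `10209` and `10209 T` are distinct atoms; the
  flag's meaning (plausibly a peripheral-blood/tissue context marker) is
  never defined, so no semantics are attached beyond identity.
* **No negation operator.** Exclusion lives on pathophem grades (`NOT`), not
  in the expression syntax.

Evaluation is Kleene three-valued: each fact is TRUE, FALSE, a number with
an optional unit, or absent (not available). FALSE dominates conjunctions,
TRUE dominates disjunctions, otherwise NA propagates. A range-constrained
atom is TRUE iff a numeric fact falls inside the range, FALSE on a value
outside it or an explicit FALSE, and NA when the code is absent *or only
known to be present* (presence without a magnitude cannot decide a range).
Units are compared only when both sides carry one; a mismatch is an error
naming both units, a bare number is treated as unitless and accepted.
`serialize_rule()` emits a canonical form (single spacing, minimal
parentheses, same-precedence children parenthesized) such that
`parse_rule(serialize_rule(ast))` is structurally the identity; the test
suite checks this on 1,000 random ASTs and checks the evaluator against an
exhaustive min/max-encoded oracle over all tri-state assignments for
expressions of up to six atoms.

## Term resolution and generalization

`resolve_term()` is total: exact label matches (case- and
diacritic-insensitive, with explicit folding of German umlauts) come first,
then terms reachable over `synonym-of` edges, and fuzzy suggestions
(normalized edit similarity ≥ 0.8, at most 5) only when nothing exact
exists. So *Nierenzyste*, *Nierencyste*, *renal cyst* and *renal cysts* all
resolve to the one code, and *renal zyst* is offered as a suggestion rather
than silently matched.

`generalize()` walks outgoing `is-a`, `is-part-of` and `is-class-of` edges
breadth-first (ties by code) up to a hop limit. `has-attribute-of` edges are
never followed: they change meaning, not granularity. A resolved query term
must also have a "primary meaning" — a hierarchical attachment or use by at
least one pathophem — otherwise verification reports a disambiguation issue
instead of guessing.

## The matching engine

A patient vector holds 1–5 elements, each a term with up to three
attributes. After verification, **strict matching** returns the pathosoms
where *every* element matches some non-excluding pathophem:

* same subject after synonym closure;
* attribute compatibility: a numeric query value must fall inside the
  pathophem's interval (closed-lower, open-upper) with compatible units,
  categories must be equal, and an ordinal level must be at or above the
  pathophem's minimum level;
* a query attribute with no same-name counterpart on the pathophem fails in
  strict mode and is forgiven in relaxed mode (this subsumes the
  attribute-free pathophem);
* any `NOT` pathophem matching any query element removes the pathosom.

**Ranking** scores a candidate as the sum over matched elements of the
matching pathophem's weight times a match-level factor — exact 1.0,
attribute-relaxed 0.8, generalized 0.6 — divided by the query length, with
ties broken by more `Lead` matches, then by id. The formula, the level
factors and the thresholds (report between 1 and 10 candidates, broaden
over at most 2 network hops) are this package's own design: the source
material specifies ranking only qualitatively, so the defaults were chosen
for determinism and monotonicity and are all configurable via
`query_config()`.

**Roll-up** removes a descendant whenever an ancestor matches with the
identical set of query elements, reporting the most general representative —
a triad of myelodysplastic findings that fits RAEB and all of RAEB-1/2/F
comes back as RAEB alone.

**Broadening** is staged and re-runs the match after every step: stage 1
drops query attributes one at a time, stage 2 generalizes each term through
the network. The drop order ("most specific first") is undefined in the
source; here cardinal qualifiers are dropped before ordinal levels before
numeric values (a free-text qualifier like *firm* is more specific than a
demographic age range), within a kind by element and declaration order. This
order also makes the breast-nodule example come out naturally: *firm* is
dropped first and the six non-firm mammary-nodule lesions are admitted. The
relaxed candidate set is a superset of the strict set at every stage.

**Narrowing** picks the next question as the candidate pathophem whose
presence count `c` across the `n` candidates minimizes `|c − n/2|` — the
most even split — with ties toward higher grade weight, then code order.
In the **dialogue** loop a TRUE answer appends the finding to the vector
(up to the 5-element limit), a FALSE answer excludes only candidates that
require the finding at `Lead` grade (a Lead finding is *always present*, so
its absence refutes the prototype; lower grades are probabilistic and
survive), and NA retires the question. The loop is fully deterministic
given the answer sequence, and terminates because every move strictly
shrinks the remaining option space (a hard iteration cap guards degenerate
configurations).

Demographic context (sex, age) is handled as ordinary query elements
matching epidemiology-class pathophems, not as hard filters.

## Fixtures and what they do (not) show

`build_cases_kb()` reconstructs four clinical clusters as a fixed, valid KB
(32 terms, 59 pathosoms): the myelodysplasia tree with the coded RAEB rule
and sibling distractors each lacking part of the query triad; the
breast-nodule cluster (the strict match plus six lesions carrying a mammary
nodule without the *firm* attribute); Meckel syndrome types 1–6 with exactly
types 1, 3 and 6 carrying polydactyly + renal cyst + encephalocele; and the
renal/fever cluster (eight febrile diseases, 25 deterministic two-symptom
distractors named `proteinuria-hematuria distractor NN` with extra findings
cycled from a fixed pool, and the MPGN subtree). The tabular pathophem
listings of the original material are not machine-readable, so the clusters
are built from the prose descriptions only; distractor content is therefore
synthetic by construction.

`generate_random_kb()` emulates a knowledge base at desk scale,
deterministically from a seed. Defaults: 20 pathosoms over 60 terms (the
emulated production system has vastly more terms than diseases, so subject
overlap between prototypes is kept low), 4–8 pathophems each, the first
always `Lead` (a prototype has a lead finding), the rest drawn from a grade
distribution (0.15/0.25/0.30/0.20/0.10 over `Lead`/`+++`/`++`/`+`/`(+)`),
one `NOT` pathophem on 20% of pathosoms, subset tree of depth ≤ 2, and
acyclic `is-a` edges pointing from higher- to lower-numbered codes. Random
KBs carry no attributes, synonyms or multilingual labels — properties
checked on them (conjunction monotonicity, NOT safety, oracle equivalence)
concern subject-level matching; attribute and synonym behavior is exercised
on the hand-built fixtures.

`generate_patient()` emits each non-excluding pathophem of a source
pathosom independently with probability `sensitivity × grade weight`,
truncates to the five highest-grade findings, and returns an attribute-free
vector. At sensitivity 1.0 every `Lead` finding is emitted, so recovery of
the source (or its roll-up ancestor) is guaranteed by construction; the
corresponding test therefore validates the pipeline's plumbing, not
clinical accuracy. At sensitivity 0 (or by bad luck at low sensitivities)
nothing is emitted, which is an error the caller must handle.

## Numerical and engineering choices

* Scores are exact floating-point sums of interval midpoints; ties are
  resolved structurally (Lead count, then id), never randomly — the engine
  contains no randomness at all.
* Serialized KBs are canonical JSON (sorted codes, stable number
  formatting): two saves of the same KB are byte-identical, and
  `save_kb()` refuses invalid KBs outright. Unknown top-level keys are
  tolerated on load for forward compatibility; an unknown schema version is
  not.
* Class codes outside the packaged taxonomy are validation *warnings*, so
  user KBs can extend the class table; everything else (arity, dangling
  subjects, non-reciprocated tree links, hierarchical cycles, rule syntax)
  is an error.
* Test-suite problem sizes were chosen to exercise the properties densely
  while keeping the default run in tens of seconds: 100 expressions × all
  tri-state assignments for the evaluator oracle, 1,000 ASTs for the
  round-trip, 200 KB/query pairs for monotonicity and NOT safety, 15 small
  KBs for the brute-force match oracle, and 10,000 replicates for the
  emission-frequency check.

## Known limitations

* No probabilistic or Bayesian posterior over diseases — scoring is a
  linguistic-evidence heuristic, and combining it with a probabilistic
  layer is explicitly out of scope.
* No free-text report parsing; the query is an already-atomized vector of
  at most five elements.
* The real licensed thesauri are not ingested; cross-references are inert
  strings, and the fixture KB is a desk-scale reconstruction, not the
  production database of thousands of prototypes.
* "Most specific first", the ranking formula, and the narrowing rule are
  principled but invented defaults; on knowledge bases with very different
  grade usage they may need retuning via `query_config()`.
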