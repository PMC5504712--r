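# pathosom

Formalized medical knowledge as prototypic disease vectors, and a
deterministic "linguistic game" that assigns a patient's findings to
candidate diagnoses.

## The problem

Clinical decision support needs a machine-readable representation of what a
disease *looks like*. `pathosom` models each disease as a **pathosom**: a
vector of **pathophems** — atomistic, coded findings such as *cytopenia*,
*bone marrow: hypercellular* or *female: aged 35–90* — each carrying at most
three attributes and an **occurrence grade**:

| grade | occurrence probability |
|-------|------------------------|
| `Lead` | exactly 1 (always present) |
| `+++`  | 0.50 – 0.99 |
| `++`   | 0.10 – 0.49 |
| `+`    | 0.01 – 0.09 |
| `(+)`  | [0, 0.01) |
| `NOT`  | the finding *excludes* the disease |

Terms live in a multilingual lexicon with cross-references into the standard
thesauri (ICD-10-GM, ICD-O, ORPHANET, OPS, LOINC, OMIM, TA, CAS, EC, HGNC,
ATC) and are connected by a typed semantic network (`is-a`, `is-part-of`,
`is-class-of`, `has-attribute-of`, `synonym-of`, plus the pathosom subset
tree). A pathosom may additionally carry a coded Boolean rule, e.g. the
myelodysplasia entity RAEB:

```
M3094|; (O812| & 10209|: 5..20%) | (10221 T| &10209 T|: 2..20%)
```

read as *refractory anemia AND ((myeloblasts AND bone marrow 5–20%) OR
(blasts AND peripheral blood 2–20%))*, evaluated in Kleene three-valued
logic (every fact is TRUE, FALSE or not available).

Diagnosis is a dialogue, not a distance computation: a patient vector of up
to five attributed terms is verified against the lexicon, matched
conjunctively against the pathosom pool, candidates are ranked by
grade-weighted evidence, equal-evidence subtrees are rolled up to their most
general member, an oversized candidate set triggers the most discriminating
follow-up question, and an empty one is broadened by dropping attributes and
generalizing terms through the semantic network (a finger finding may match
a hand-level prototype).

## Worked example

The packaged fixture KB reconstructs four worked clinical clusters
(myelodysplasia, breast nodule, Meckel syndrome, renal/fever):

```r
library(pathosom)
kb <- build_cases_kb()
kb
#> <knowledge_base> 32 terms, 59 pathosoms (186 pathophems), 34 edges

pv <- patient_vector("cytopenia", "anemia",
  query_element("bone marrow", list(attribute("cellularity", "hypercellular"))))
run_query(pv, kb)
#>  pathosom_id                                           name score n_matched n_missing
#>        M3501 RAEB (refractory anemia with excess of blasts) 0.915         3         0
```

The three findings intersect on the whole RAEB subtree (RAEB and its
RAEB-1/2/F subsets); roll-up reports only the most general representative,
so a single diagnosis is returned with score 0.915 (two `Lead` matches and
one `+++` match, averaged over the three query elements). Its coded rule
confirms a concrete lab constellation:

```r
eval_rule(kb$pathosoms[["M3501"]]$rule,
          list(M3094 = TRUE, O812 = TRUE, `10209` = list(value = 12, unit = "%")))
#> [1] TRUE
```

The dialogue loop narrows an oversized candidate set by asking questions.
Proteinuria + hematuria alone leave 34 candidates; the engine asks about
fever (the most even split), and a TRUE answer reduces the set to the eight
febrile renal diseases:

```r
out <- dialogue(patient_vector("proteinuria", "hematuria"), kb,
                answer_provider = function(sug) if (sug$term_code == "F1032") TRUE else NA)
out$transcript
#>   step action detail answer n_candidates
#> 1    1    ask  F1032   TRUE           34
as.data.frame(out$results)[1:3, ]
#>   pathosom_id                             name score n_matched n_missing
#> 1       F2301 cryoglobulinemia with vasculitis 0.445         3         0
#> 2       F2302            periarteriitis nodosa 0.445         3         0
#> 3       F2303         microscopic polyangiitis 0.445         3         0
```

A command-line front end ships under `inst/cli/pathosom-cli.R`
(subcommands `validate`, `stats`, `query`, `dialogue`, `evaluate`,
`expr eval`, `fixtures ...`).

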