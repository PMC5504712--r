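raeb_rule <- "M3094|; (O812| & 10209|: 5..20%) | (10221 T| &10209 T|: 2..20%)"

test_that("the myelodysplasia rule parses to the documented shape", {
  ast <- parse_rule(raeb_rule)
  expect_identical(ast$variant, "SEQ")
  expect_length(ast$children, 2)
  expect_identical(ast$children[[1]],
                   expr_atom("M3094"))
  alt <- ast$children[[2]]
  expect_identical(alt$variant, "OR")
  expect_length(alt$children, 2)
  left <- alt$children[[1]]
  expect_identical(left$variant, "AND")
  expect_identical(left$children[[1]]$code, "O812")
  expect_identical(left$children[[2]]$constraint,
                   range_constraint(5, 20, "%"))
  right <- alt$children[[2]]
  expect_identical(right$children[[1]]$code, "10221")
  expect_identical(right$children[[1]]$flag, "T")
  expect_identical(right$children[[2]]$flag, "T")
  expect_identical(right$children[[2]]$constraint,
                   range_constraint(2, 20, "%"))
})

test_that("trivial and malformed expressions", {
  expect_identical(parse_rule("M3094|"), expr_atom("M3094"))
  err <- expect_error(parse_rule("M3094|; &"), class = "dsl_syntax_error")
  expect_match(conditionMessage(err), "position")
  expect_error(parse_rule("  "), "empty expression")
  expect_error(parse_rule("(M3094|"), class = "dsl_syntax_error")
  expect_error(parse_rule("M3094| M3095|"), class = "dsl_syntax_error")
})

test_that("three-valued evaluation of the myelodysplasia rule", {
  # facts: refractory anemia present, myeloblasts present, marrow blasts 12%
  expect_true(eval_rule(raeb_rule, list(
    M3094 = TRUE, O812 = TRUE, `10209` = list(value = 12, unit = "%"))))
  # a FALSE top-level conjunct dominates everything else
  expect_false(eval_rule(raeb_rule, list(M3094 = FALSE)))
  expect_false(eval_rule(raeb_rule, list(
    M3094 = FALSE, O812 = TRUE, `10209` = list(value = 12, unit = "%"))))
  # nothing known: not available
  expect_identical(eval_rule(raeb_rule, list()), NA)
  # blasts out of range on one branch, other branch unknown -> NA
  expect_identical(eval_rule(raeb_rule, list(
    M3094 = TRUE, O812 = TRUE, `10209` = list(value = 35, unit = "%"))), NA)
  # both branches refuted -> FALSE
  expect_false(eval_rule(raeb_rule, list(
    M3094 = TRUE, O812 = FALSE, `10221 T` = FALSE)))
})

test_that("range constraints are closed-lower, open-upper", {
  ast <- parse_rule("10209|: 5..20%")
  f <- function(v) eval_rule(ast, list(`10209` = list(value = v, unit = "%")))
  expect_true(f(5))
  expect_true(f(19.9))
  expect_false(f(20))
  expect_false(f(4.9))
  # presence known without a magnitude cannot decide the constraint
  expect_identical(eval_rule(ast, list(`10209` = TRUE)), NA)
  expect_false(eval_rule(ast, list(`10209` = FALSE)))
})

test_that("unit mismatches are evaluation errors naming both units", {
  ast <- parse_rule("10209|: 5..20%")
  err <- expect_error(
    eval_rule(ast, list(`10209` = list(value = 12, unit = "g/l"))))
  expect_match(conditionMessage(err), "g/l")
  expect_match(conditionMessage(err), "%")
  # a bare (unitless) number is accepted
  expect_true(eval_rule(ast, list(`10209` = 12)))
})

test_that("serialization is canonical and guards arity", {
  expect_identical(serialize_rule(expr_atom("M3094")), "M3094|")
  rt <- parse_rule(serialize_rule(parse_rule(raeb_rule)))
  expect_identical(rt, parse_rule(raeb_rule))
  one_child <- structure(list(variant = "OR", children = list(
    expr_atom("M3094"))), class = "expr_node")
  expect_error(serialize_rule(one_child), "at least 2 children")
  nested_seq <- expr_and(expr_seq(expr_atom("A1"), expr_atom("A2")),
                         expr_atom("A3"))
  expect_error(serialize_rule(nested_seq), "root")
})

test_that("parse-serialize is the identity on random ASTs", {
  set.seed(101)
  for (i in 1:200) {
    ast <- gen_ast_full()
    expect_identical(parse_rule(serialize_rule(ast)), ast)
  }
})

test_that("evaluator agrees with the min/max Kleene oracle exhaustively", {
  set.seed(202)
  for (i in 1:40) {
    ast <- gen_ast_plain(sample(1:4, 1))
    keys <- expr_atom_keys(ast)
    for (assignment in all_assignments(keys)) {
      expect_identical(eval_rule(ast, assignment_to_facts(assignment)),
                       oracle_eval(ast, assignment))
    }
  }
})

test_that("information is monotone: refining NA never un-decides a result", {
  set.seed(303)
  for (i in 1:50) {
    ast <- gen_ast_plain(sample(2:5, 1))
    keys <- expr_atom_keys(ast)
    assignment <- stats::setNames(
      as.list(sample(c(TRUE, FALSE, NA), length(keys), replace = TRUE)), keys)
    base <- eval_rule(ast, assignment_to_facts(assignment))
    if (is.na(base)) next
    for (k in keys[vapply(assignment, is.na, logical(1))]) {
      for (v in c(TRUE, FALSE)) {
        refined <- assignment
        refined[[k]] <- v
        expect_identical(eval_rule(ast, assignment_to_facts(refined)), base)
      }
    }
  }
})

test_that("a FALSE SEQ conjunct dominates regardless of the other atoms", {
  set.seed(404)
  for (i in 1:25) {
    clause <- gen_ast_plain(3)
    ast <- expr_seq(expr_atom("Z9"), clause)
    keys <- setdiff(expr_atom_keys(ast), "Z9")
    assignment <- stats::setNames(
      as.list(sample(c(TRUE, FALSE, NA), length(keys), replace = TRUE)), keys)
    assignment[["Z9"]] <- FALSE
    expect_false(eval_rule(ast, assignment_to_facts(assignment)))
  }
})
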