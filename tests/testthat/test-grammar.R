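test_that("the production inventory is the fixed 24-rule grammar", {
  g <- sql_grammar()
  expect_equal(nrow(g), 24L)
  expect_equal(sum(g$lhs == "A"), 7L)
  expect_equal(sum(g$lhs == "Filter" & !g$tag %in% c("and", "or")), 9L)
  expect_equal(sum(g$lhs == "Z"), 1L)
  known <- c("Z", "R", "Select", "A", "Filter", "C", "T", "V")
  expect_true(all(unlist(g$rhs) %in% known))
  expect_false(anyDuplicated(g$id) > 0)
})

test_that("a single-column no-where query serializes to exactly 6 actions", {
  sch <- fx_schema()
  tree <- sql_to_tree('select demographic."insurance" from demographic', sch)
  acts <- tree_to_actions(tree)
  expect_length(acts, 6L)
  expect_equal(vapply(acts, `[[`, character(1), "t"),
               c("rule", "rule", "rule", "rule", "col", "tab"))
})

test_that("the running example serializes depth-first left-to-right", {
  sch <- fx_schema()
  q <- paste('select demographic."insurance", demographic."diagnosis"',
             'from demographic where demographic."name" = "james sloan"')
  tree <- sql_to_tree(q, sch)
  toks <- tokenize_question(
    "tell me the insurance and primary disease of james sloan")
  acts <- tree_to_actions(tree, toks)
  g <- sql_grammar()
  cols <- schema_columns(sch)
  # prefix: Z->R, R->Select Filter, Select->A A, A->none C T, col, tab
  expect_equal(acts[[1]], action_rule(g$id[g$lhs == "Z"]))
  expect_equal(g$lhs[acts[[2]]$id], "R")
  expect_length(g$rhs[[acts[[2]]$id]], 2L)
  expect_length(g$rhs[[acts[[3]]$id]], 2L)
  expect_equal(g$tag[acts[[4]]$id], "none")
  expect_equal(cols$qualified[acts[[5]]$id], "demographic.insurance")
  expect_equal(acts[[6]]$t, "tab")
  # the value span points at "james sloan" (0-based, inclusive)
  val <- acts[[length(acts)]]
  expect_equal(val$t, "val")
  expect_identical(toks[(val$start + 1):(val$end + 1)], c("james", "sloan"))
})

test_that("malformed action sequences fail with the offending position", {
  expect_error(actions_to_tree(list(action_col(1))),
               class = "medsql_sequence_error")
  expect_error(actions_to_tree(list(action_col(1))), "position 1")
  sch <- fx_schema()
  tree <- sql_to_tree('select demographic."age" from demographic', sch)
  acts <- tree_to_actions(tree)
  expect_error(actions_to_tree(acts[1:4]), class = "medsql_sequence_error")
  expect_error(actions_to_tree(c(acts, list(action_tab(1)))),
               class = "medsql_sequence_error")
})

test_that("value leaves absent from the question are rejected", {
  sch <- fx_schema()
  tree <- sql_to_tree(
    'select demographic."age" from demographic where demographic."name" = "zz top"',
    sch)
  expect_error(tree_to_actions(tree, c("who", "is", "here")),
               class = "medsql_value_error")
})

test_that("valid_actions tracks the grammar frontier", {
  sch <- fx_schema()
  g <- sql_grammar()
  st <- init_decode_state()
  va <- valid_actions(st, sch, g)
  expect_equal(va$kind, "rule")
  expect_identical(va$rule_ids, g$id[g$lhs == "Z"])
  # walk to an A frontier
  st <- apply_action(st, action_rule(g$id[g$lhs == "Z"]), sch, g)
  st <- apply_action(st, action_rule(g$id[g$lhs == "R"][1]), sch, g)
  st <- apply_action(st, action_rule(g$id[g$lhs == "Select"][1]), sch, g)
  va <- valid_actions(st, sch, g)
  expect_length(va$rule_ids, 7L)
  # select a column, then only its table is admissible
  st <- apply_action(st, action_rule(va$rule_ids[1]), sch, g)
  cols <- schema_columns(sch)
  ins <- cols$id[cols$qualified == "demographic.insurance"]
  st <- apply_action(st, action_col(ins), sch, g)
  va <- valid_actions(st, sch, g)
  expect_equal(va$kind, "tab")
  expect_identical(va$tab_ids, match("demographic", schema_tables(sch)))
})

test_that("the table-candidate universe of the bundled schema has 5 entries", {
  expect_length(schema_tables(fx_schema()), 5L)
})

test_that("tree <-> actions round trip is the identity on random trees", {
  sch <- fx_schema()
  set.seed(1234)
  n_ok <- 0L
  for (i in 1:300) {
    cs <- random_tree_case(sch)
    acts <- tree_to_actions(cs$tree)
    back <- actions_to_tree(acts)
    if (identical(back, cs$tree)) n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 300L)
})

test_that("any sequence accepted step-by-step parses as a tree", {
  sch <- fx_schema()
  g <- sql_grammar()
  set.seed(99)
  for (i in 1:50) {
    # random walk through valid_actions
    st <- init_decode_state(128L)
    acts <- list()
    n_tok <- 12L
    while (!medsql:::state_done(st)) {
      va <- valid_actions(st, sch, g, n_tokens = n_tok)
      a <- switch(va$kind,
        rule = {
          ids <- va$rule_ids
          # keep recursion in check
          if (st$step > 40L) ids <- setdiff(ids, g$id[g$tag %in% c("and", "or")])
          action_rule(sample(ids, 1))
        },
        col = action_col(sample(va$col_ids, 1)),
        tab = action_tab(va$tab_ids[1]),
        val = {
          s <- sample.int(n_tok, 1) - 1L
          action_val(s, min(n_tok - 1L, s + sample(0:2, 1)))
        })
      st <- apply_action(st, a, sch, g)
      acts[[length(acts) + 1L]] <- a
    }
    expect_silent(actions_to_tree(acts))
  }
})

test_that("actions serialize to JSON lines and back", {
  acts <- list(action_rule(3L), action_col(12L), action_tab(1L),
               action_val(2L, 4L))
  expect_identical(actions_from_json(actions_to_json(acts)), acts)
})
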