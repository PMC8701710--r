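test_that("SQL parses into the expected tree shapes", {
  sch <- fx_schema()
  g <- sql_grammar()
  q <- paste('select demographic."insurance", demographic."diagnosis"',
             'from demographic where demographic."name" = "james sloan"')
  tree <- sql_to_tree(q, sch)
  r <- tree$children[[1]]
  expect_length(r$children, 2L)              # R -> Select Filter
  expect_length(r$children[[1]]$children, 2L) # Select -> A A
  expect_equal(g$tag[r$children[[2]]$prod], "eq")

  t2 <- sql_to_tree(paste('select min(demographic."days_stay") from demographic',
                          'where demographic."dob_year" > "2200"'), sch)
  sel <- t2$children[[1]]$children[[1]]
  expect_equal(g$tag[sel$children[[1]]$prod], "min")
  expect_equal(g$tag[t2$children[[1]]$children[[2]]$prod], "gt")

  t3 <- sql_to_tree(paste('select count(distinct demographic."subject_id")',
                          'from demographic'), sch)
  expect_equal(g$tag[t3$children[[1]]$children[[1]]$children[[1]]$prod],
               "count_distinct")
})

test_that("unsupported constructs are named in the error", {
  sch <- fx_schema()
  expect_error(
    sql_to_tree(paste('select demographic."age" from demographic',
                      'group by demographic."age"'), sch),
    class = "medsql_unsupported_error")
  expect_error(
    sql_to_tree('select demographic."age" from demographic limit 5', sch),
    "limit")
  expect_error(sql_to_tree('select demographic."nope" from demographic', sch),
               class = "medsql_lookup_error")
})

test_that("rendering builds the From clause over the shortest join path", {
  sch <- fx_schema()
  tree <- sql_to_tree(paste(
    'select diagnoses."icd9_code" from diagnoses',
    'inner join demographic on diagnoses.hadm_id = demographic.hadm_id',
    'where demographic."name" = "john gartman"'), sch)
  out <- tree_to_sql(tree, sch)
  expect_match(out$sql,
               "inner join demographic on diagnoses.hadm_id = demographic.hadm_id",
               fixed = TRUE)
  # single-table tree: no join clause
  t1 <- sql_to_tree('select demographic."age" from demographic', sch)
  expect_false(grepl("join", tree_to_sql(t1, sch)$sql))
})

test_that("unconnectable tables raise a join-path error", {
  sch <- medsql_schema(
    tables = list(
      list(name = "a", columns = data.frame(name = c("x", "k"), kind = "text",
                                            join_key = c(FALSE, TRUE))),
      list(name = "b", columns = data.frame(name = c("y", "k"), kind = "text",
                                            join_key = c(FALSE, TRUE)))),
    joins = data.frame(left = "a", right = "b", key = "k"))
  tree <- sql_to_tree(
    'select a."x" from a inner join b on a.k = b.k where b."y" = "v"', sch)
  sch_cut <- sch
  sch_cut$joins <- sch_cut$joins[0, ]
  expect_error(tree_to_sql(tree, sch_cut), class = "medsql_join_error")
})

test_that("canonicalization normalizes case, whitespace and quotes", {
  a <- 'SELECT demographic."age"  FROM demographic'
  b <- "select demographic.“age” from demographic"
  expect_identical(canonicalize_sql(a), canonicalize_sql(b))
  expect_identical(canonicalize_sql('x."y" <> "3"'),
                   canonicalize_sql('x."y" != "3"'))
})

test_that("canonicalization keeps order-sensitive distinctions", {
  cs <- case_study_pairs()
  # join order (pair 1) and select-column order (pair 2) both differ
  expect_false(identical(canonicalize_sql(cs$gold[1]), canonicalize_sql(cs$pred[1])))
  expect_false(identical(canonicalize_sql(cs$gold[2]), canonicalize_sql(cs$pred[2])))
})

test_that("tree <-> SQL round trip is the identity on random trees", {
  sch <- fx_schema()
  set.seed(4321)
  n_ok <- 0L
  for (i in 1:300) {
    cs <- random_tree_case(sch)
    t_text <- tree_with_text_values(cs$tree, cs$tokens)
    sql <- tree_to_sql(t_text, sch)$sql
    back <- sql_to_tree(sql, sch)
    if (identical(back, t_text)) n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 300L)
})

test_that("generated gold SQL re-parses to the generating tree", {
  gen <- fx_gen()
  for (e in gen$examples[1:50]) {
    tree <- sql_to_tree(e$sql, gen$schema)
    acts <- tree_to_actions(tree, e$tokens)
    expect_identical(
      lapply(acts, function(a) a[setdiff(names(a), c("span_s", "span_e"))]),
      lapply(e$actions, function(a) a[setdiff(names(a), c("span_s", "span_e"))]))
  }
})
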