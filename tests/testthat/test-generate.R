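test_that("the generated schema matches the EMR shape", {
  sch <- make_schema()
  expect_length(sch$tables, 5L)
  expect_equal(unname(vapply(sch$tables, function(t) nrow(t$columns), integer(1))),
               c(23L, 5L, 5L, 7L, 9L))
  expect_true(medsql:::schema_connected(sch))
})

test_that("record sampling is deterministic with referential integrity", {
  sch <- fx_schema()
  r1 <- sample_records(sch, 50, seed = 7)
  r2 <- sample_records(sch, 50, seed = 7)
  expect_identical(r1, r2)
  for (tab in c("diagnoses", "procedures", "prescriptions", "lab")) {
    expect_true(all(r1[[tab]]$hadm_id %in% r1$demographic$hadm_id))
  }
  expect_lte(length(unique(r1$demographic$name)), 50L)
})

test_that("generated pairs parse, convert and execute at 100%", {
  gen <- fx_gen()
  sch <- gen$schema
  ok_parse <- ok_exec <- ok_actions <- 0L
  for (e in gen$examples) {
    tree <- tryCatch(sql_to_tree(e$sql, sch), medsql_error = function(err) NULL)
    if (!is.null(tree)) ok_parse <- ok_parse + 1L
    r <- tryCatch(execute_query(gen$db, e$sql),
                  medsql_exec_error = function(err) NULL)
    if (!is.null(r)) ok_exec <- ok_exec + 1L
    back <- tryCatch(actions_to_tree(e$actions), medsql_error = function(err) NULL)
    if (!is.null(back)) ok_actions <- ok_actions + 1L
  }
  n <- length(gen$examples)
  expect_equal(ok_parse, n)
  expect_equal(ok_exec, n)
  expect_equal(ok_actions, n)
})

test_that("splits follow the configured ratios and the seed", {
  sch <- fx_schema()
  rec <- sample_records(sch, 40, seed = 2)
  gen <- generate_pairs(sch, rec, gen_config(n_pairs = 1000, n_patients = 40,
                                             seed = 2))
  on.exit(close_db(gen$db))
  splits <- table(vapply(gen$examples, `[[`, character(1), "split"))
  expect_equal(splits[["train"]], 800L)
  expect_equal(splits[["val"]], 100L)
  expect_equal(splits[["test"]], 100L)
  # determinism
  gen2 <- generate_pairs(sch, rec, gen_config(n_pairs = 50, n_patients = 40,
                                              seed = 9))
  gen3 <- generate_pairs(sch, rec, gen_config(n_pairs = 50, n_patients = 40,
                                              seed = 9))
  on.exit(close_db(gen2$db), add = TRUE)
  on.exit(close_db(gen3$db), add = TRUE)
  expect_identical(gen2$examples, gen3$examples)
})

test_that("zero paraphrase rate reproduces template questions verbatim", {
  sch <- fx_schema()
  rec <- sample_records(sch, 30, seed = 3)
  gen <- generate_pairs(sch, rec, gen_config(n_pairs = 60, n_patients = 30,
                                             seed = 3, paraphrase_rate = 0))
  on.exit(close_db(gen$db))
  # every value span must be present verbatim and every question must end
  # in template punctuation (no dropout applied)
  for (e in gen$examples) {
    expect_true(e$tokens[length(e$tokens)] %in% c(".", "?"))
  }
})

test_that("a 500-pair corpus exercises every grammar production", {
  sch <- fx_schema()
  rec <- sample_records(sch, 60, seed = 4)
  gen <- generate_pairs(sch, rec, gen_config(n_pairs = 500, n_patients = 60,
                                             seed = 4))
  on.exit(close_db(gen$db))
  used <- unique(unlist(lapply(gen$examples, function(e)
    vapply(e$actions, function(a) if (a$t == "rule") a$id else NA_integer_,
           integer(1)))))
  expect_setequal(stats::na.omit(used), sql_grammar()$id)
})

test_that("corpus statistics sit near the target query shape", {
  gen <- fx_gen()
  g <- sql_grammar()
  sel_arity <- vapply(gen$examples, function(e) {
    ids <- vapply(e$actions, function(a) if (a$t == "rule") a$id else NA_integer_,
                  integer(1))
    sid <- ids[!is.na(ids) & g$lhs[ids] == "Select"][1]
    length(g$rhs[[sid]])
  }, numeric(1))
  cmp_ids <- g$id[g$lhs == "Filter" & !g$tag %in% c("and", "or")]
  n_cond <- vapply(gen$examples, function(e) {
    sum(vapply(e$actions, function(a) a$t == "rule" && a$id %in% cmp_ids,
               logical(1)))
  }, numeric(1))
  expect_lt(abs(mean(sel_arity) - 1.1), 0.3)
  expect_lt(abs(mean(n_cond) - 1.76), 0.3)
})

test_that("corpora round-trip through the JSON-lines format", {
  gen <- fx_gen()
  path <- tempfile(fileext = ".jsonl")
  write_corpus(gen$examples[1:20], path)
  back <- read_corpus(path)
  expect_length(back, 20L)
  for (i in 1:20) {
    expect_identical(back[[i]]$sql, gen$examples[[i]]$sql)
    expect_identical(back[[i]]$tokens, gen$examples[[i]]$tokens)
    expect_identical(back[[i]]$actions, gen$examples[[i]]$actions)
  }
  unlink(path)
})
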