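test_that("bundled schema config loads with the expected shape", {
  path <- system.file("extdata", "mimicsql_like.yaml", package = "medsql")
  sch <- load_schema(path)
  expect_s3_class(sch, "medsql_schema")
  expect_length(sch$tables, 5L)
  expect_equal(unname(vapply(sch$tables, function(t) nrow(t$columns), integer(1))),
               c(23L, 5L, 5L, 7L, 9L))
  expect_identical(schema_tables(sch),
                   c("demographic", "diagnoses", "procedures",
                     "prescriptions", "lab"))
})

test_that("schema validation accepts trivial graphs and rejects bad joins", {
  one <- medsql_schema(list(list(name = "t", columns = data.frame(
    name = "a", kind = "text", join_key = FALSE))))
  expect_s3_class(one, "medsql_schema")
  expect_error(
    medsql_schema(
      tables = list(
        list(name = "a", columns = data.frame(name = "x", kind = "text",
                                              join_key = FALSE)),
        list(name = "b", columns = data.frame(name = "y", kind = "text",
                                              join_key = FALSE))),
      joins = data.frame(left = "a", right = "b", key = "missing")),
    class = "medsql_schema_error")
  # disconnected graph
  expect_error(
    medsql_schema(
      tables = list(
        list(name = "a", columns = data.frame(name = "x", kind = "text",
                                              join_key = FALSE)),
        list(name = "b", columns = data.frame(name = "y", kind = "text",
                                              join_key = FALSE)))),
    class = "medsql_schema_error")
  expect_error(load_schema(tempfile()), class = "medsql_parse_error")
})

test_that("fixture databases hold the inserted rows and are reproducible", {
  sch <- fx_tiny_schema()
  rec <- list(
    people = data.frame(person_id = 1:10,
                        full_name = paste("Person", 1:10),
                        insurance = rep(c("Private", "Medicare"), 5),
                        days_stay = 1:10),
    visits = data.frame(person_id = 1:10, reason = rep("checkup", 10)))
  db <- build_fixture_db(sch, rec)
  on.exit(close_db(db), add = TRUE)
  r <- execute_query(db, "select count(*) from people")
  expect_equal(r$rows[[1]][[1]], 10)
  # text values are lower-cased at load
  expect_true(all(lookup_values(db, "people", "insurance") %in%
                    c("private", "medicare")))

  empty <- build_fixture_db(sch, list())
  on.exit(close_db(empty), add = TRUE)
  expect_equal(execute_query(empty, "select count(*) from visits")$rows[[1]][[1]], 0)

  # same records and path produce identical probe results
  p1 <- file.path(tempdir(), "fx1.sqlite")
  probe <- 'select people."full_name", people."days_stay" from people where people."days_stay" > "3"'
  db1 <- build_fixture_db(sch, rec, p1)
  r1 <- execute_query(db1, probe)
  close_db(db1)
  db2 <- build_fixture_db(sch, rec, p1)
  r2 <- execute_query(db2, probe)
  close_db(db2)
  expect_identical(r1, r2)
  unlink(p1)

  bad <- list(people = data.frame(person_id = "not a number",
                                  full_name = "x", insurance = "y",
                                  days_stay = "z"))
  expect_error(build_fixture_db(sch, bad), class = "medsql_load_error")
})

test_that("query execution signals failures instead of crashing", {
  db <- case_study_fixture()
  on.exit(close_db(db))
  r <- execute_query(db,
    'select count(distinct demographic."subject_id") from demographic')
  expect_equal(r$rows[[1]][[1]], 4)
  expect_error(execute_query(db, "select bogus from"),
               class = "medsql_exec_error")
  expect_error(execute_query(db, "not sql at all"),
               class = "medsql_exec_error")
})

test_that("join order does not change execution results", {
  db <- case_study_fixture()
  on.exit(close_db(db))
  cs <- case_study_pairs()
  rg <- execute_query(db, cs$gold[1])
  rp <- execute_query(db, cs$pred[1])
  expect_true(results_equal(rg, rp))
})

test_that("lookup_values returns distinct stored values in first-seen order", {
  sch <- fx_tiny_schema()
  rec <- list(people = data.frame(
    person_id = 1:4,
    full_name = c("John Gartman", "Walter Locher", "John Gartman", "Ann B"),
    insurance = "x", days_stay = 1))
  db <- build_fixture_db(sch, rec)
  on.exit(close_db(db))
  v <- lookup_values(db, "people", "full_name")
  expect_identical(v, c("john gartman", "walter locher", "ann b"))
  expect_identical(lookup_values(db, "visits", "reason"), character(0))
  expect_error(lookup_values(db, "people", "nope"),
               class = "medsql_lookup_error")
})

test_that("repeated execution of one query is deterministic", {
  gen <- fx_gen()
  sqls <- vapply(gen$examples[1:20], `[[`, character(1), "sql")
  for (s in sqls) {
    expect_identical(execute_query(gen$db, s), execute_query(gen$db, s))
  }
})
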