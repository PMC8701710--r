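# A tiny model configuration keeps these structural checks fast.
fx_model <- function(gen = fx_gen(), seed = 5) {
  vocab <- build_vocab(gen$examples, gen$schema)
  medsql_model(vocab, gen$schema,
               model_config(enc_dim = 16, enc_layers = 1, enc_heads = 2,
                            dec_dim = 20), seed = seed)
}

test_that("input serialization starts with CLS and counts add up", {
  sch <- fx_schema()
  toks <- tokenize_question("tell me the insurance of james sloan.")
  mq <- link_schema(toks, sch)
  stream <- serialize_input(mq, sch)
  expect_identical(stream$tokens[1], "[cls]")
  cols <- schema_columns(sch)
  # brute-force counter: cls + question words + one mark per span + 1 sep
  # + (column words + 1 sep each) + (table words + 1 sep each)
  expected <- 1L + length(toks) + length(mq$spans) + 1L +
    sum(vapply(cols$column, function(cn) length(medsql:::name_words(cn)) + 1L,
               integer(1))) +
    sum(vapply(schema_tables(sch),
               function(tn) length(medsql:::name_words(tn)) + 1L, integer(1)))
  expect_length(stream$tokens, expected)
  expect_length(stream$q_spans, length(mq$spans))
  expect_length(stream$col_pos, nrow(cols))
  expect_length(stream$tab_pos, 5L)
  # an empty question is degenerate but legal
  s0 <- serialize_input(link_schema(character(0), sch), sch)
  expect_identical(s0$tokens[1:2], c("[cls]", "[sep]"))
})

test_that("encoding is deterministic and shaped by the input", {
  gen <- fx_gen()
  model <- fx_model(gen)
  toks <- gen$examples[[1]]$tokens
  stream <- serialize_input(link_schema(toks, gen$schema), gen$schema)
  e1 <- encode(stream, model)
  e2 <- encode(stream, model)
  expect_identical(e1$H_X, e2$H_X)
  expect_identical(e1$h_cls, e2$h_cls)
  expect_equal(nrow(e1$H_C), nrow(schema_columns(gen$schema)))
  expect_equal(nrow(e1$H_T), 5L)
  expect_equal(nrow(e1$H_X), length(stream$q_spans))
  expect_true(all(is.finite(e1$H_X)))
})

test_that("column encodings are equivariant under within-table reordering", {
  gen <- fx_gen()
  model <- fx_model(gen)
  sch <- gen$schema
  sch2 <- sch
  cs <- sch2$tables$demographic$columns
  i1 <- match("insurance", cs$name); i2 <- match("religion", cs$name)
  cs[c(i1, i2), ] <- cs[c(i2, i1), ]
  sch2$tables$demographic$columns <- cs
  toks <- tokenize_question("how many patients were admitted in the year 2120 or later?")
  e1 <- encode(serialize_input(link_schema(toks, sch), sch), model)
  e2 <- encode(serialize_input(link_schema(toks, sch2), sch2), model)
  perm <- match(schema_columns(sch)$qualified, schema_columns(sch2)$qualified)
  expect_equal(e1$H_C, e2$H_C[perm, ], tolerance = 1e-12)
  expect_equal(e1$H_X, e2$H_X, tolerance = 1e-12)
})

test_that("decoder initialization is tanh-bounded and zero at zero", {
  gen <- fx_gen()
  model <- fx_model(gen)
  st <- init_decoder(numeric(model$config$enc_dim) * 0, model)
  # bcls starts at zero, so a zero CLS vector gives a zero hidden state
  expect_equal(st$h, numeric(model$config$dec_dim))
  stream <- serialize_input(link_schema(gen$examples[[1]]$tokens, gen$schema),
                            gen$schema)
  enc <- encode(stream, model)
  st2 <- init_decoder(enc$h_cls, model)
  expect_true(all(st2$h > -1 & st2$h < 1))
  expect_identical(st2$h, init_decoder(enc$h_cls, model)$h)
})

test_that("step distributions are normalized over the admissible set", {
  gen <- fx_gen()
  model <- fx_model(gen)
  ex <- gen$examples[[2]]
  dists <- model_step_dists(ex, model, gen$schema)
  prep <- prepare_example(ex, model, gen$schema)
  g <- sql_grammar()
  for (i in seq_along(dists)) {
    d <- dists[[i]]
    stp <- prep$steps[[i]]
    if (d$kind == "rule") {
      expect_equal(sum(d$p), 1, tolerance = 1e-6)
      expect_true(all(d$p[!stp$mask] == 0))
    } else if (d$kind == "col") {
      expect_equal(sum(d$p), 1, tolerance = 1e-6)
    } else if (d$kind == "tab") {
      expect_equal(sum(d$p), 1, tolerance = 1e-6)
      expect_true(all(d$p[!stp$mask] == 0))
    } else {
      expect_equal(sum(d$p_start), 1, tolerance = 1e-6)
      expect_equal(sum(d$p_end), 1, tolerance = 1e-6)
    }
  }
})

test_that("a selected column moves from the schema branch to memory", {
  gen <- fx_gen()
  model <- fx_model(gen)
  sch <- gen$schema
  # a query whose condition column repeats: insurance = x or insurance = y
  cols <- schema_columns(sch)
  ins <- cols$id[cols$qualified == "demographic.insurance"]
  sql <- paste('select demographic."age" from demographic',
               'where demographic."insurance" = "private"',
               'or demographic."insurance" = "medicare"')
  toks <- tokenize_question(
    "what is the age of patients with insurance private or insurance medicare?")
  tree <- sql_to_tree(sql, sch)
  ex <- list(tokens = toks, actions = tree_to_actions(tree, toks), sql = sql)
  prep <- prepare_example(ex, model, sch)
  col_steps <- which(vapply(prep$steps, function(s) s$kind == "col", logical(1)))
  golds <- vapply(prep$steps[col_steps], `[[`, integer(1), "gold")
  second_ins <- col_steps[which(golds == ins)[2]]
  stp <- prep$steps[[second_ins]]
  expect_true(stp$mem_mask[ins])    # reachable through memory
  expect_false(stp$sch_mask[ins])   # removed from the schema branch
  dists <- model_step_dists(ex, model, sch)
  d <- dists[[second_ins]]$p
  expect_gt(d[ins], 0)              # still selectable overall
  # and the schema-branch probability of a memory column is exactly zero:
  # verified through the masks above plus normalization of the mixture
  expect_equal(sum(d), 1, tolerance = 1e-6)
})

test_that("analytic gradients match finite differences on a tiny model", {
  sch <- fx_tiny_schema()
  rec <- list(
    people = data.frame(person_id = 1:3,
                        full_name = c("ann ray", "bo lee", "cy dole"),
                        insurance = c("private", "medicare", "self"),
                        days_stay = c(3, 9, 27)),
    visits = data.frame(person_id = 1:3, reason = c("checkup", "pain", "cough")))
  sql <- paste('select people."insurance" from people',
               'where people."full_name" = "bo lee"')
  toks <- tokenize_question("tell me the insurance of bo lee.")
  tree <- sql_to_tree(sql, sch)
  ex <- list(tokens = toks, actions = tree_to_actions(tree, toks), sql = sql)
  vocab <- build_vocab(list(ex), sch)
  model <- medsql_model(vocab, sch,
                        model_config(enc_dim = 8, enc_layers = 2,
                                     enc_heads = 2, dec_dim = 8), seed = 2)
  prep <- prepare_example(ex, model, sch)
  ge <- grad_env()
  enc <- encode(prep$stream, model, keep_cache = TRUE)
  teacher_pass(model, prep, enc, ge = ge)
  grads <- grads_as_list(ge)
  lossfn <- function(m) teacher_pass(m, prep, encode(prep$stream, m))$loss
  eps <- 1e-5
  set.seed(8)
  for (nm in c("Wr", "Wsch", "Wvs", "Wve", "lstm_Wx", "Wax", "Wac",
               "Wpool", "Wcls", "Etok", "l1_Wq", "l2_W2", "Eseg")) {
    p <- model$params[[nm]]
    for (k in sample(length(p), 3)) {
      m2 <- model; m2$params[[nm]][k] <- p[k] + eps
      m3 <- model; m3$params[[nm]][k] <- p[k] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      ana <- grads[[nm]][k]
      expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("greedy constrained decoding always yields executable SQL", {
  gen <- fx_gen()
  sch <- gen$schema
  vocab <- build_vocab(gen$examples, sch)
  set.seed(60)
  qs <- vapply(gen$examples[sample(length(gen$examples), 25)],
               function(e) detokenize(e$tokens), character(1))
  for (s in 1:4) {
    model <- medsql_model(vocab, sch,
                          model_config(enc_dim = 16, enc_layers = 1,
                                       enc_heads = 2, dec_dim = 20),
                          seed = 1000 + s)
    for (q in qs) {
      out <- infer_sql(q, model, sch, db = gen$db)
      expect_silent(execute_query(gen$db, out$sql))
    }
  }
})
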