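within_split <- function(e, s) { e$split <- s; e }

test_that("sequence loss follows the closed form on uniform distributions", {
  gen <- fx_gen()
  model <- medsql_model(build_vocab(gen$examples, gen$schema), gen$schema,
                        model_config(enc_dim = 16, enc_layers = 1,
                                     enc_heads = 2, dec_dim = 20), seed = 1)
  ex <- gen$examples[[1]]
  prep <- prepare_example(ex, model, gen$schema)
  n_tok <- length(ex$tokens)
  # hand-built uniform distributions over each step's admissible set
  dists <- lapply(seq_along(prep$steps), function(i) {
    stp <- prep$steps[[i]]
    if (stp$kind == "rule") {
      p <- numeric(24); p[stp$mask] <- 1 / sum(stp$mask)
      list(kind = "rule", p = p)
    } else if (stp$kind == "col") {
      nc <- length(stp$sch_mask)
      list(kind = "col", p = rep(1 / nc, nc))
    } else if (stp$kind == "tab") {
      p <- numeric(5); p[stp$mask] <- 1 / sum(stp$mask)
      list(kind = "tab", p = p)
    } else {
      list(kind = "val", p_start = rep(1 / n_tok, n_tok),
           p_end = rep(1 / n_tok, n_tok))
    }
  })
  expected <- 0
  for (i in seq_along(prep$steps)) {
    stp <- prep$steps[[i]]
    expected <- expected + switch(stp$kind,
      rule = log(sum(stp$mask)),
      col = log(length(stp$sch_mask)),
      tab = log(sum(stp$mask)),
      val = 2 * log(n_tok))
  }
  expect_equal(sequence_loss(ex$actions, dists), expected, tolerance = 1e-12)
  # perfect distributions give zero loss
  perfect <- lapply(seq_along(prep$steps), function(i) {
    stp <- prep$steps[[i]]
    a <- ex$actions[[i]]
    if (stp$kind == "val") {
      ps <- numeric(n_tok); ps[a$start + 1] <- 1
      pe <- numeric(n_tok); pe[a$end + 1] <- 1
      list(kind = "val", p_start = ps, p_end = pe)
    } else {
      p <- numeric(max(24, length(stp$sch_mask %||% 0), 5))
      p[a$id] <- 1
      list(kind = stp$kind, p = p)
    }
  })
  expect_equal(sequence_loss(ex$actions, perfect), 0)
})

test_that("model losses decrease as gold probabilities rise", {
  gen <- fx_gen()
  model <- medsql_model(build_vocab(gen$examples, gen$schema), gen$schema,
                        model_config(enc_dim = 16, enc_layers = 1,
                                     enc_heads = 2, dec_dim = 20), seed = 1)
  ex <- gen$examples[[3]]
  dists <- model_step_dists(ex, model, gen$schema)
  base <- sequence_loss(ex$actions, dists)
  expect_gte(base, 0)
  # nudging a non-saturated gold probability upward lowers the loss
  k <- which(vapply(seq_along(dists), function(i) {
    d <- dists[[i]]
    d$kind != "val" && d$p[ex$actions[[i]]$id] < 0.999
  }, logical(1)))[1]
  d2 <- dists
  d2[[k]]$p <- d2[[k]]$p * 0.5
  d2[[k]]$p[ex$actions[[k]]$id] <- d2[[k]]$p[ex$actions[[k]]$id] + 0.5
  expect_lt(sequence_loss(ex$actions, d2), base)
})

test_that("training memorizes a single example and is seed-reproducible", {
  sch <- fx_schema()
  rec <- sample_records(sch, 20, seed = 55)
  gen <- generate_pairs(sch, rec, gen_config(n_pairs = 12, n_patients = 20,
                                             seed = 55, paraphrase_rate = 0))
  on.exit(close_db(gen$db))
  one <- gen$examples[[1]]
  one$split <- "train"
  corpus <- list(one, within_split(gen$examples[[1]], "val"))
  vocab <- build_vocab(corpus, sch)
  cfg <- model_config(enc_dim = 16, enc_layers = 1, enc_heads = 2, dec_dim = 24)
  tcfg <- train_config(lr = 5e-3, epochs = 40, batch_size = 1, seed = 9)
  m1 <- medsql_model(vocab, sch, cfg, seed = 9)
  ck1 <- train_model(corpus, m1, tcfg, sch, quiet = TRUE)
  pred <- infer_sql(detokenize(one$tokens), ck1$model, sch, db = gen$db)$sql
  expect_identical(canonicalize_sql(pred), canonicalize_sql(one$sql))
  # identical seeds give identical training trajectories
  m2 <- medsql_model(vocab, sch, cfg, seed = 9)
  ck2 <- train_model(corpus, m2, tcfg, sch, quiet = TRUE)
  expect_identical(ck1$history, ck2$history)
  expect_identical(ck1$model$params$Wr, ck2$model$params$Wr)
})

test_that("checkpoints round-trip and verify the grammar fingerprint", {
  gen <- fx_gen()
  vocab <- build_vocab(gen$examples, gen$schema)
  model <- medsql_model(vocab, gen$schema,
                        model_config(enc_dim = 16, enc_layers = 1,
                                     enc_heads = 2, dec_dim = 20), seed = 1)
  ckpt <- structure(list(model = model, history = data.frame(),
                         train_cfg = train_config()),
                    class = "medsql_checkpoint")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ckpt, path)
  back <- load_checkpoint(path)
  expect_identical(back$model$params$Wr, model$params$Wr)
  # corrupt the stored grammar: loading must refuse
  bad <- ckpt
  bad$model$grammar <- bad$model$grammar[1:20, ]
  save_checkpoint(bad, path)
  expect_error(load_checkpoint(path), class = "medsql_config_error")
  unlink(path)
})
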