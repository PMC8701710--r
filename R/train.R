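# Teacher-forced maximum-likelihood training: each question-SQL pair is
# converted to a gold action sequence; the decoder is driven along the
# gold prefix and the negative log-likelihood of the gold actions is
# minimized with Adam under global gradient-norm clipping.

#' Training configuration
#'
#' The desk-scale learning rate (5e-4) suits the small from-scratch
#' encoder; fine-tuning a pretrained-transformer backend would use a much
#' smaller rate (order 1e-6) over ~100 epochs. Batch size 8 and clip norm
#' 5 follow the decoder's usual regime.
#'
#' @param lr Learning rate.
#' @param epochs Maximum epochs.
#' @param batch_size Examples per gradient step.
#' @param clip_norm Global gradient-norm clip.
#' @param seed Seed controlling shuffling (model init has its own seed).
#' @param val_limit Cap on validation examples scored per epoch.
#' @param stop_acc Stop early once validation Acc_LF reaches this value.
#' @param lr_decay Multiplicative per-epoch learning-rate decay (1 = none);
#'   lets a large initial rate settle instead of oscillating at a plateau.
#' @return A `medsql_trainconfig` list.
#' @export
train_config <- function(lr = 5e-4, epochs = 15L, batch_size = 8L,
                         clip_norm = 5.0, seed = 42L, val_limit = 200L,
                         stop_acc = 0.999, lr_decay = 1) {
  stopifnot(lr > 0, epochs >= 1L, batch_size >= 1L, clip_norm > 0,
            lr_decay > 0, lr_decay <= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 seed = as.integer(seed), val_limit = val_limit,
                 stop_acc = stop_acc, lr_decay = lr_decay),
            class = "medsql_trainconfig")
}

#' Prepare a training example for the decoder
#'
#' Links and serializes the question, then replays the gold action
#' sequence through the grammar state machine, recording per step the
#' frontier kind, admissibility masks, gold indices (value spans are
#' aligned from token indices to encoder spans), and the previous action.
#' A gold action outside the admissible set raises `medsql_data_error`.
#'
#' @param example List with `tokens` and `actions`.
#' @param model A `medsql_model` (for configuration only).
#' @param schema A `medsql_schema`.
#' @return A prep object consumed by the training pass.
#' @export
prepare_example <- function(example, model, schema) {
  grammar <- model$grammar
  mq <- link_schema(example$tokens, schema)
  stream <- serialize_input(mq, schema)
  froms <- vapply(stream$q_spans, `[[`, integer(1), "from")
  tos <- vapply(stream$q_spans, `[[`, integer(1), "to")
  n_rules <- nrow(grammar)
  n_cols <- model$n_columns
  n_tabs <- length(model$schema_tables)
  state <- init_decode_state(model$config$max_actions)
  steps <- vector("list", length(example$actions))
  prev <- NULL
  for (i in seq_along(example$actions)) {
    a <- example$actions[[i]]
    top <- state$stack[1]
    if (a$t == "rule") {
      mask <- grammar$lhs == top
      if (!mask[a$id])
        medsql_error("medsql_data_error",
                     sprintf("gold rule %d inadmissible at step %d", a$id, i))
      steps[[i]] <- list(kind = "rule", mask = mask, gold = a$id, prev = prev)
    } else if (a$t == "col") {
      mem <- seq_len(n_cols) %in% state$memory
      steps[[i]] <- list(kind = "col", sch_mask = !mem, mem_mask = mem,
                         gold = a$id, prev = prev)
    } else if (a$t == "tab") {
      va <- valid_actions(state, schema, grammar)
      mask <- seq_len(n_tabs) %in% va$tab_ids
      if (!mask[a$id])
        medsql_error("medsql_data_error",
                     sprintf("gold table %d inadmissible at step %d", a$id, i))
      steps[[i]] <- list(kind = "tab", mask = mask, gold = a$id, prev = prev)
    } else {
      gs <- match(a$start + 1L, froms)
      ge_ <- match(a$end + 1L, tos)
      if (is.na(gs) || is.na(ge_) || ge_ < gs)
        medsql_error("medsql_data_error",
                     sprintf("gold value span (%d,%d) does not align with question spans at step %d",
                             a$start, a$end, i))
      steps[[i]] <- list(kind = "val", gold_s = gs, gold_e = ge_, prev = prev)
      a$span_s <- gs; a$span_e <- ge_
    }
    state <- apply_action(state, a, schema, grammar)
    prev <- a
  }
  if (!state_done(state))
    medsql_error("medsql_data_error", "gold action sequence is incomplete")
  list(stream = stream, steps = steps, tokens = example$tokens,
       sql = example$sql)
}

#' Negative log-likelihood of a gold action sequence
#'
#' Given per-step action distributions (value steps carry `p_start` and
#' `p_end` over question tokens), returns the summed negative log
#' probability of the gold actions; value spans contribute both pointer
#' terms.
#'
#' @param actions Gold action list.
#' @param dists Per-step distributions, as produced by
#'   [model_step_dists()].
#' @return Nonnegative scalar.
#' @export
sequence_loss <- function(actions, dists) {
  stopifnot(length(actions) == length(dists))
  loss <- 0
  for (i in seq_along(actions)) {
    a <- actions[[i]]; d <- dists[[i]]
    pg <- if (a$t == "val") d$p_start[a$start + 1L] * d$p_end[a$end + 1L]
          else d$p[a$id]
    if (is.na(pg) || pg <= 0)
      medsql_error("medsql_data_error",
                   sprintf("gold action at step %d has zero probability", i))
    loss <- loss - log(pg)
  }
  loss
}

#' Per-step action distributions under teacher forcing
#'
#' Runs the encoder and the decoder along the gold action prefix and
#' returns each step's full distribution over the admissible actions
#' (probability exactly 0 elsewhere).
#'
#' @param example List with `tokens` and `actions`.
#' @param model A trained or fresh `medsql_model`.
#' @param schema A `medsql_schema`.
#' @return List of per-step distributions.
#' @export
model_step_dists <- function(example, model, schema) {
  prep <- prepare_example(example, model, schema)
  enc <- encode(prep$stream, model, keep_cache = FALSE)
  teacher_pass(model, prep, enc, ge = NULL, want_dists = TRUE)$dists
}

# Adam ----------------------------------------------------------------------

#' @keywords internal
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

#' @keywords internal
adam_step <- function(params, grads, state, lr, clip_norm,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  sq <- 0
  for (nm in names(grads)) sq <- sq + sum(grads[[nm]]^2)
  gnorm <- sqrt(sq)
  scale <- if (gnorm > clip_norm) clip_norm / gnorm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    if (!all(is.finite(g)))
      medsql_error("medsql_train_error",
                   sprintf("non-finite gradient in '%s'; training diverged", nm))
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the encoder-decoder on a corpus
#'
#' Teacher-forced maximum likelihood with Adam and per-batch global
#' gradient clipping. Model selection keeps the parameters with the best
#' validation logic-form accuracy (greedy decoding); training stops early
#' once that accuracy reaches `stop_acc`.
#'
#' @param corpus Example list (each with `tokens`, `actions`, `sql`,
#'   `split`); `train` examples are fitted, `val` examples drive model
#'   selection.
#' @param model A fresh `medsql_model`.
#' @param cfg A [train_config()].
#' @param schema A `medsql_schema`.
#' @param quiet Suppress per-epoch messages.
#' @return A `medsql_checkpoint`: `model` (best parameters), `history`
#'   (per-epoch loss and validation accuracy), `train_cfg`.
#' @export
train_model <- function(corpus, model, cfg = train_config(), schema,
                        quiet = FALSE) {
  train_ex <- Filter(function(e) e$split == "train", corpus)
  val_ex <- Filter(function(e) e$split == "val", corpus)
  if (length(train_ex) == 0L)
    medsql_error("medsql_input_error", "corpus has no training examples")
  preps <- lapply(train_ex, prepare_example, model = model, schema = schema)
  if (length(val_ex) > cfg$val_limit) val_ex <- val_ex[seq_len(cfg$val_limit)]
  set.seed(cfg$seed)
  opt <- adam_init(model$params)
  best <- list(acc = -1, params = model$params)
  history <- data.frame(epoch = integer(), loss = numeric(), val_acc_lf = numeric())
  lr_decay <- cfg$lr_decay %||% 1
  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- cfg$lr * lr_decay^(ep - 1L)
    ord <- sample(length(preps))
    total <- 0
    for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
      bi <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
      ge <- grad_env()
      for (j in bi) {
        prep <- preps[[j]]
        enc <- encode(prep$stream, model, keep_cache = TRUE)
        total <- total + teacher_pass(model, prep, enc, ge = ge)$loss
      }
      grads <- grads_as_list(ge)
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(bi)
      upd <- adam_step(model$params, grads, opt, lr_ep, cfg$clip_norm)
      model$params <- upd$params
      opt <- upd$state
    }
    val_acc <- if (length(val_ex)) {
      preds <- vapply(val_ex, function(e) {
        tryCatch(infer_sql(detokenize(e$tokens), model, schema)$sql,
                 medsql_error = function(err) "")
      }, character(1))
      golds <- vapply(val_ex, `[[`, character(1), "sql")
      acc_lf(preds, golds)$acc
    } else NA_real_
    history <- rbind(history, data.frame(epoch = ep,
                                         loss = total / length(preps),
                                         val_acc_lf = val_acc))
    if (!quiet)
      message(sprintf("epoch %d  loss %.4f  val Acc_LF %.3f",
                      ep, total / length(preps), val_acc))
    if (!is.na(val_acc) && val_acc > best$acc) {
      best$acc <- val_acc
      best$params <- model$params
    }
    if (!is.na(val_acc) && val_acc >= cfg$stop_acc) break
  }
  if (best$acc >= 0) model$params <- best$params
  structure(list(model = model, history = history, train_cfg = cfg),
            class = "medsql_checkpoint")
}

#' Save / load a checkpoint
#'
#' Checkpoints carry the parameters, configuration, vocabulary and the
#' grammar production table; loading verifies the stored grammar against
#' the package's and refuses on mismatch.
#'
#' @param ckpt A `medsql_checkpoint`.
#' @param path File path.
#' @return `path` / the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!isTRUE(all.equal(ckpt$model$grammar, sql_grammar())))
    medsql_error("medsql_config_error",
                 "checkpoint grammar fingerprint does not match this package")
  ckpt
}
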