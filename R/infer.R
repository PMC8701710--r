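# Greedy constrained inference: at every step the model's distribution is
# masked to the grammar-admissible actions, so any parameter setting -
# including random initialization - yields a parseable action sequence
# that renders to engine-accepted SQL.

#' Generate SQL for a question
#'
#' Runs schema linking, encoding, and greedy grammar-constrained decoding;
#' the resulting action sequence is parsed into an IR tree and rendered to
#' SQL. When a database handle is supplied, extracted condition values on
#' text-kind columns are recovered against stored content by ROUGE-L.
#' Decoding that exceeds `max_len` raises `medsql_length_error`
#' (incomplete output). Near the length budget, recursive connective
#' productions are masked out so a completion always exists.
#'
#' @param question Question text.
#' @param model A trained `medsql_model` (a fresh one decodes too, just
#'   badly).
#' @param schema A `medsql_schema`.
#' @param db Optional `medsql_db` for value recovery.
#' @param max_len Maximum action-sequence length.
#' @return List with `sql`, `actions`, `tree`.
#' @export
infer_sql <- function(question, model, schema, db = NULL, max_len = NULL) {
  grammar <- model$grammar
  max_len <- max_len %||% model$config$max_actions
  tokens <- tokenize_question(question)
  if (length(tokens) == 0L)
    medsql_error("medsql_input_error", "empty question")
  mq <- link_schema(tokens, schema)
  stream <- serialize_input(mq, schema)
  enc <- encode(stream, model, keep_cache = FALSE)
  P <- model$params
  froms <- vapply(stream$q_spans, `[[`, integer(1), "from")
  tos <- vapply(stream$q_spans, `[[`, integer(1), "to")
  n_cols <- model$n_columns
  recursive_rules <- grammar$id[!is.na(grammar$tag) & grammar$tag %in% c("and", "or")]

  state <- init_decode_state(max_len)
  dec <- init_decoder(enc$h_cls, model)
  M <- rbind(enc$H_C, enc$H_T)
  h <- dec$h; c0 <- dec$c
  prev <- NULL
  actions <- list()
  while (!state_done(state)) {
    va <- valid_actions(state, schema, grammar, n_tokens = length(tokens))
    ai <- action_input(P, enc, prev)
    core <- dec_core(P, ai$x, h, c0, enc, M)
    if (va$kind == "rule") {
      mask <- grammar$id %in% va$rule_ids
      # keep a completion within budget: every pending symbol needs >= 1
      # action, an A subtree needs 3, a comparison >= 6
      budget <- max_len - state$step
      if (budget < 6L * length(state$stack) + 12L) {
        trimmed <- mask & !(grammar$id %in% recursive_rules)
        if (any(trimmed)) mask <- trimmed
      }
      p <- head_rule(P, core, mask)$p
      a <- action_rule(which.max(p))
    } else if (va$kind == "col") {
      mem <- seq_len(n_cols) %in% state$memory
      p <- head_col(P, core, enc, sch_mask = !mem, mem_mask = mem)$p
      a <- action_col(which.max(p))
    } else if (va$kind == "tab") {
      mask <- seq_along(model$schema_tables) %in% va$tab_ids
      p <- head_tab(P, core, enc, mask)$p
      a <- action_tab(which.max(p))
    } else {
      hs <- head_val_start(P, core, enc)
      s_span <- which.max(hs$p)
      he <- head_val_end(P, core, enc, s_span)
      e_span <- which.max(he$p)
      a <- action_val(froms[s_span] - 1L, tos[e_span] - 1L)
      a$span_s <- s_span; a$span_e <- e_span
    }
    state <- apply_action(state, a, schema, grammar)
    actions[[length(actions) + 1L]] <- a
    prev <- a
    h <- core$h; c0 <- core$c
  }
  tree <- actions_to_tree(actions, grammar, max_len = max_len)
  if (!is.null(db)) tree <- recover_tree_values(tree, tokens, db, model$grammar)
  rendered <- tree_to_sql(tree, schema, tokens, grammar)
  list(sql = rendered$sql, actions = actions, tree = tree)
}

# Replace extracted value spans with database-recovered text on text-kind
# condition columns; numeric columns keep the extracted token text.
#' @keywords internal
recover_tree_values <- function(tree, tokens, db, grammar) {
  cols <- schema_columns(db$schema)
  fix <- function(node) {
    if (node$sym %in% c("Z", "R", "Select")) {
      node$children <- lapply(node$children, fix)
    } else if (node$sym == "Filter") {
      tag <- grammar$tag[node$prod]
      if (tag %in% c("and", "or")) {
        node$children <- lapply(node$children, fix)
      } else {
        cid <- node$children[[1]]$children[[1]]$col
        for (k in seq_along(node$children)[-1]) {
          v <- node$children[[k]]
          txt <- if (!is.null(v$text)) v$text
                 else detokenize(tokens[(v$start + 1L):(v$end + 1L)])
          node$children[[k]]$text <- recover_value(txt, db, cols$table[cid],
                                                   cols$column[cid])
        }
      }
    }
    node
  }
  fix(tree)
}

#' Generate SQL for a batch of questions
#'
#' @param questions Character vector.
#' @inheritParams infer_sql
#' @param on_error Value recorded for a question whose decoding fails.
#' @return Character vector of SQL texts.
#' @export
predict_sql <- function(questions, model, schema, db = NULL, on_error = "") {
  vapply(questions, function(q) {
    tryCatch(infer_sql(q, model, schema, db)$sql,
             medsql_error = function(e) on_error)
  }, character(1), USE.NAMES = FALSE)
}
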