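# The context-free grammar of the tree-structured intermediate
# representation. A query tree is rooted at Z; R chooses whether a Where
# clause exists; Select carries 1-3 aggregation nodes A; each A is an
# aggregator tag plus a column leaf C and table leaf T; Filter is a boolean
# tree of comparisons over (A, value-span V) pairs.
#
# Serialization of a tree as an action sequence is depth-first,
# left-to-right: ApplyRule for internal nodes, SelectColumn / SelectTable /
# SelectValue for the terminal leaves.

AGG_TAGS <- c("none", "max", "min", "count", "sum", "avg", "count_distinct")
OP_TAGS  <- c("eq", "ne", "gt", "ge", "lt", "le", "like", "nlike")
NONTERMS <- c("Z", "R", "Select", "A", "Filter")

#' The production inventory of the query grammar
#'
#' Exactly 24 productions: `Z -> R`; `R -> Select [Filter]`;
#' `Select -> A | A A | A A A`; seven aggregator productions
#' `A -> agg C T`; `and`/`or` connectives; eight binary comparison
#' operators `Filter -> op A V`; and `Filter -> between A V V`.
#'
#' @return A data frame with columns `id`, `lhs`, `tag` and list-column
#'   `rhs` (the child symbols, tags excluded).
#' @export
sql_grammar <- function() {
  p <- list()
  add <- function(lhs, tag, rhs) p[[length(p) + 1L]] <<- list(lhs = lhs, tag = tag, rhs = rhs)
  add("Z", NA_character_, c("R"))
  add("R", NA_character_, c("Select"))
  add("R", NA_character_, c("Select", "Filter"))
  add("Select", NA_character_, c("A"))
  add("Select", NA_character_, c("A", "A"))
  add("Select", NA_character_, c("A", "A", "A"))
  for (a in AGG_TAGS) add("A", a, c("C", "T"))
  add("Filter", "and", c("Filter", "Filter"))
  add("Filter", "or", c("Filter", "Filter"))
  for (o in OP_TAGS) add("Filter", o, c("A", "V"))
  add("Filter", "between", c("A", "V", "V"))
  data.frame(
    id = seq_along(p),
    lhs = vapply(p, `[[`, character(1), "lhs"),
    tag = vapply(p, `[[`, character(1), "tag"),
    rhs = I(lapply(p, `[[`, "rhs")),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
grammar_rule_id <- function(grammar, lhs, tag = NA_character_, n_children = NULL) {
  hit <- grammar$lhs == lhs &
    (is.na(tag) & is.na(grammar$tag) | !is.na(tag) & !is.na(grammar$tag) & grammar$tag == tag)
  if (!is.null(n_children))
    hit <- hit & vapply(grammar$rhs, length, integer(1)) == n_children
  id <- grammar$id[hit]
  if (length(id) != 1L)
    medsql_error("medsql_grammar_error",
                 sprintf("no unique production for lhs=%s tag=%s", lhs, tag))
  id
}

# Tree node constructors ---------------------------------------------------

#' @keywords internal
ir_node <- function(sym, prod, children) {
  list(sym = sym, prod = prod, children = children)
}

#' @keywords internal
ir_leaf_c <- function(col_id) list(sym = "C", col = as.integer(col_id))

#' @keywords internal
ir_leaf_t <- function(tab_id) list(sym = "T", tab = as.integer(tab_id))

# A value leaf carries either the literal text (trees parsed from SQL) or a
# 0-based inclusive token span into the question (trees built from actions).
#' @keywords internal
ir_leaf_v <- function(text = NULL, start = NULL, end = NULL) {
  v <- list(sym = "V")
  if (!is.null(text)) v$text <- text
  if (!is.null(start)) { v$start <- as.integer(start); v$end <- as.integer(end) }
  v
}

# Action constructors ------------------------------------------------------

#' Construct decoder actions
#'
#' The four action types of the grammar-based decoder: apply a production,
#' pick a schema-qualified column, pick a table, or pick a question token
#' span as a condition value (0-based, inclusive).
#'
#' @param id Production / column / table id.
#' @param start,end Token indices for value spans.
#' @return A list with element `t` (one of `"rule"`, `"col"`, `"tab"`,
#'   `"val"`) plus its payload.
#' @name actions
NULL

#' @rdname actions
#' @export
action_rule <- function(id) list(t = "rule", id = as.integer(id))
#' @rdname actions
#' @export
action_col <- function(id) list(t = "col", id = as.integer(id))
#' @rdname actions
#' @export
action_tab <- function(id) list(t = "tab", id = as.integer(id))
#' @rdname actions
#' @export
action_val <- function(start, end) {
  stopifnot(start <= end)
  list(t = "val", start = as.integer(start), end = as.integer(end))
}

# Decoding state -----------------------------------------------------------

# The frontier is a stack of pending symbols (top = position 1). `last_col`
# feeds table pruning; `memory` records selected columns in order.

#' Initial decoding state
#' @param max_len Maximum action-sequence length before decoding aborts.
#' @return A `medsql_state` list.
#' @export
init_decode_state <- function(max_len = 128L) {
  structure(list(stack = "Z", last_col = NA_integer_, memory = integer(),
                 step = 0L, max_len = as.integer(max_len)),
            class = "medsql_state")
}

#' @keywords internal
state_done <- function(state) length(state$stack) == 0L

#' Admissible actions at a decoding state
#'
#' Returns exactly the actions whose application keeps the partial
#' sequence grammar-consistent. For a nonterminal frontier these are the
#' productions sharing that left-hand side; for a `C` frontier, every
#' schema column (the model splits them into unselected-schema and memory
#' branches); for a `T` frontier, only tables containing the column just
#' selected; for a `V` frontier, token spans of the question.
#'
#' @param state A `medsql_state`.
#' @param schema A `medsql_schema`.
#' @param grammar Production table from [sql_grammar()].
#' @param n_tokens Number of question tokens (bounds value spans).
#' @return A list with `kind` (`"rule"`, `"col"`, `"tab"`, `"val"` or
#'   `"done"`) and the admissible ids (`rule_ids`, `col_ids` with
#'   `in_memory` flags, `tab_ids`, or `n_tokens`).
#' @export
valid_actions <- function(state, schema, grammar = sql_grammar(), n_tokens = NULL) {
  if (state_done(state)) return(list(kind = "done"))
  top <- state$stack[1]
  if (top %in% NONTERMS) {
    list(kind = "rule", rule_ids = grammar$id[grammar$lhs == top])
  } else if (top == "C") {
    cols <- schema_columns(schema)
    list(kind = "col", col_ids = cols$id, in_memory = cols$id %in% state$memory)
  } else if (top == "T") {
    cols <- schema_columns(schema)
    if (is.na(state$last_col))
      medsql_error("medsql_grammar_error", "table frontier with no selected column")
    tab <- cols$table[state$last_col]
    list(kind = "tab", tab_ids = match(tab, schema_tables(schema)))
  } else if (top == "V") {
    list(kind = "val", n_tokens = n_tokens)
  } else {
    medsql_error("medsql_grammar_error", sprintf("unknown frontier symbol '%s'", top))
  }
}

#' Apply one action to a decoding state
#'
#' @inheritParams valid_actions
#' @param action An action from [action_rule()] and friends.
#' @return The updated state.
#' @export
apply_action <- function(state, action, schema, grammar = sql_grammar()) {
  if (state_done(state))
    medsql_error("medsql_sequence_error",
                 sprintf("action at position %d after tree completion", state$step + 1L))
  if (state$step + 1L > state$max_len)
    medsql_error("medsql_length_error", "maximum action-sequence length exceeded")
  top <- state$stack[1]
  rest <- state$stack[-1]
  if (action$t == "rule") {
    if (!top %in% NONTERMS || grammar$lhs[action$id] != top)
      medsql_error("medsql_sequence_error",
                   sprintf("rule %d does not expand frontier '%s' at position %d",
                           action$id, top, state$step + 1L))
    state$stack <- c(grammar$rhs[[action$id]], rest)
  } else if (action$t == "col") {
    if (top != "C")
      medsql_error("medsql_sequence_error",
                   sprintf("SelectColumn at non-column frontier '%s' at position %d",
                           top, state$step + 1L))
    state$stack <- rest
    state$last_col <- action$id
    if (!action$id %in% state$memory) state$memory <- c(state$memory, action$id)
  } else if (action$t == "tab") {
    if (top != "T")
      medsql_error("medsql_sequence_error",
                   sprintf("SelectTable at non-table frontier '%s' at position %d",
                           top, state$step + 1L))
    state$stack <- rest
  } else if (action$t == "val") {
    if (top != "V")
      medsql_error("medsql_sequence_error",
                   sprintf("SelectValue at non-value frontier '%s' at position %d",
                           top, state$step + 1L))
    state$stack <- rest
  } else {
    medsql_error("medsql_sequence_error", sprintf("unknown action type '%s'", action$t))
  }
  state$step <- state$step + 1L
  state
}

# Tree <-> actions ---------------------------------------------------------

#' Serialize an IR tree as an action sequence
#'
#' Depth-first, left-to-right. Value leaves that carry literal text are
#' located in the question tokens (first contiguous occurrence of their
#' token sequence); leaves that already carry a span pass it through.
#'
#' @param tree An IR tree (from [sql_to_tree()] or [actions_to_tree()]).
#' @param tokens Question tokens ([tokenize_question()]); required when any
#'   value leaf carries text rather than a span.
#' @return List of actions.
#' @export
tree_to_actions <- function(tree, tokens = NULL) {
  out <- list()
  walk <- function(node) {
    if (node$sym %in% NONTERMS) {
      out[[length(out) + 1L]] <<- action_rule(node$prod)
      for (ch in node$children) walk(ch)
    } else if (node$sym == "C") {
      out[[length(out) + 1L]] <<- action_col(node$col)
    } else if (node$sym == "T") {
      out[[length(out) + 1L]] <<- action_tab(node$tab)
    } else if (node$sym == "V") {
      if (!is.null(node$start)) {
        out[[length(out) + 1L]] <<- action_val(node$start, node$end)
      } else {
        span <- find_token_span(node$text, tokens)
        if (is.null(span))
          medsql_error("medsql_value_error",
                       sprintf("condition value '%s' not found in question", node$text))
        out[[length(out) + 1L]] <<- action_val(span[1], span[2])
      }
    }
  }
  walk(tree)
  out
}

# First contiguous occurrence of the value's token sequence in the
# question; returns 0-based inclusive (start, end) or NULL.
#' @keywords internal
find_token_span <- function(text, tokens) {
  if (is.null(tokens)) return(NULL)
  vt <- tokenize_question(text)
  k <- length(vt)
  if (k == 0L || k > length(tokens)) return(NULL)
  low <- tolower(tokens)
  for (s in seq_len(length(tokens) - k + 1L)) {
    if (all(low[s:(s + k - 1L)] == vt)) return(c(s - 1L, s + k - 2L))
  }
  NULL
}

#' Reconstruct the IR tree from an action sequence
#'
#' Inverse of [tree_to_actions()]. A sequence that violates the grammar
#' (wrong action type at the frontier, rule with mismatched left-hand
#' side, or premature end) raises `medsql_sequence_error` naming the
#' failing position.
#'
#' @param actions List of actions.
#' @param grammar Production table.
#' @param max_len Maximum admissible length.
#' @return The IR tree.
#' @export
actions_to_tree <- function(actions, grammar = sql_grammar(), max_len = 128L) {
  if (length(actions) > max_len)
    medsql_error("medsql_length_error", "action sequence exceeds maximum length")
  pos <- 0L
  nxt <- function() {
    pos <<- pos + 1L
    if (pos > length(actions))
      medsql_error("medsql_sequence_error",
                   sprintf("action sequence ends prematurely at position %d", pos))
    actions[[pos]]
  }
  build <- function(sym) {
    a <- nxt()
    if (sym %in% NONTERMS) {
      if (a$t != "rule" || grammar$lhs[a$id] != sym)
        medsql_error("medsql_sequence_error",
                     sprintf("expected a production for '%s' at position %d", sym, pos))
      ir_node(sym, a$id, lapply(grammar$rhs[[a$id]], build))
    } else if (sym == "C") {
      if (a$t != "col")
        medsql_error("medsql_sequence_error",
                     sprintf("expected SelectColumn at position %d", pos))
      ir_leaf_c(a$id)
    } else if (sym == "T") {
      if (a$t != "tab")
        medsql_error("medsql_sequence_error",
                     sprintf("expected SelectTable at position %d", pos))
      ir_leaf_t(a$id)
    } else {
      if (a$t != "val")
        medsql_error("medsql_sequence_error",
                     sprintf("expected SelectValue at position %d", pos))
      ir_leaf_v(start = a$start, end = a$end)
    }
  }
  tree <- build("Z")
  if (pos != length(actions))
    medsql_error("medsql_sequence_error",
                 sprintf("trailing actions after tree completion at position %d", pos + 1L))
  tree
}

# JSON-lines serialization of action sequences (training-data format).

#' Serialize actions as JSON lines
#' @param actions List of actions.
#' @return Character vector, one JSON object per action.
#' @export
actions_to_json <- function(actions) {
  vapply(actions, function(a) jsonlite::toJSON(a, auto_unbox = TRUE), character(1))
}

#' Parse actions from JSON lines
#' @param lines Character vector of JSON objects.
#' @return List of actions.
#' @export
actions_from_json <- function(lines) {
  lapply(lines, function(l) {
    a <- jsonlite::fromJSON(l)
    if (a$t == "val") action_val(a$start, a$end)
    else if (a$t == "rule") action_rule(a$id)
    else if (a$t == "col") action_col(a$id)
    else action_tab(a$id)
  })
}
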