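# SQL <-> IR tree conversions for the supported query subset
# (select / aggregates / inner joins / where with and-or comparisons),
# plus the deterministic canonical rendering used by logic-form accuracy.

AGG_KEYWORDS <- c("max", "min", "count", "sum", "avg")
UNSUPPORTED_KEYWORDS <- c("group", "order", "limit", "union", "intersect",
                          "except", "having")

# Tokenizer shared by the parser and canonicalize_sql(): quoted strings are
# kept whole (flagged), multi-char comparison operators are single tokens.
#' @keywords internal
sql_tokens <- function(sql) {
  x <- gsub("[“”]", "\"", sql)
  x <- gsub("[‘’]", "'", x)
  pat <- "\"[^\"]*\"|'[^']*'|<=|>=|!=|<>|[(),.=<>]|[^[:space:](),.=<>!\"']+"
  m <- gregexpr(pat, x)[[1]]
  if (m[1] == -1L) return(data.frame(text = character(), quoted = logical()))
  toks <- regmatches(x, gregexpr(pat, x))[[1]]
  quoted <- grepl("^[\"']", toks)
  inner <- ifelse(quoted, substr(toks, 2, nchar(toks) - 1L), toks)
  data.frame(text = inner, quoted = quoted, stringsAsFactors = FALSE)
}

#' Canonicalize SQL text for logic-form comparison
#'
#' Lower-cases, normalizes whitespace and quote style (quoted strings are
#' split into their words), and maps `<>` to `!=`. Token order is
#' preserved, so select-column order and join-table order still
#' distinguish queries.
#'
#' @param sql SQL text.
#' @return Character vector of canonical tokens.
#' @export
canonicalize_sql <- function(sql) {
  tk <- sql_tokens(sql)
  out <- character()
  for (i in seq_len(nrow(tk))) {
    t <- tolower(tk$text[i])
    if (tk$quoted[i]) {
      out <- c(out, strsplit(trimws(t), "\\s+")[[1]])
    } else {
      if (t == "<>") t <- "!="
      out <- c(out, t)
    }
  }
  out[nzchar(out)]
}

# Recursive-descent parser ------------------------------------------------

#' @keywords internal
parse_sql_query <- function(sql) {
  tk <- sql_tokens(sql)
  pos <- 1L
  peek <- function(k = 0L) {
    if (pos + k > nrow(tk)) return(NULL)
    tolower(tk$text[pos + k])
  }
  peek_quoted <- function() pos <= nrow(tk) && tk$quoted[pos]
  advance <- function() {
    t <- tk[pos, ]
    pos <<- pos + 1L
    t
  }
  expect <- function(word) {
    t <- peek()
    if (is.null(t) || t != word)
      medsql_error("medsql_syntax_error",
                   sprintf("expected '%s' near token %d ('%s')", word, pos, t %||% "<end>"))
    advance()
  }
  fail_unsupported <- function(word) {
    medsql_error("medsql_unsupported_error",
                 sprintf("unsupported SQL construct: '%s'", word))
  }
  check_unsupported <- function() {
    t <- peek()
    if (!is.null(t) && !peek_quoted() && t %in% UNSUPPORTED_KEYWORDS)
      fail_unsupported(t)
  }

  colref <- function() {
    tab <- tolower(advance()$text)
    expect(".")
    col <- tolower(advance()$text)
    list(table = tab, column = col)
  }
  select_item <- function() {
    t <- peek()
    if (!peek_quoted() && t %in% AGG_KEYWORDS) {
      agg <- advance()$text
      expect("(")
      distinct <- FALSE
      if (identical(peek(), "distinct") && !peek_quoted()) { advance(); distinct <- TRUE }
      cr <- colref()
      expect(")")
      tag <- tolower(agg)
      if (distinct) {
        if (tag != "count") fail_unsupported(paste0(tag, "(distinct)"))
        tag <- "count_distinct"
      }
      c(cr, list(agg = tag))
    } else {
      c(colref(), list(agg = "none"))
    }
  }
  value <- function() {
    if (pos > nrow(tk))
      medsql_error("medsql_syntax_error", "expected a value at end of input")
    tolower(advance()$text)
  }
  cond_prim <- function() {
    if (identical(peek(), "(") && !peek_quoted()) {
      advance()
      c0 <- cond_or()
      expect(")")
      return(c0)
    }
    cr <- colref()
    t <- peek()
    if (identical(t, "not") && !peek_quoted()) {
      advance(); expect("like")
      return(list(type = "cmp", op = "nlike", table = cr$table,
                  column = cr$column, values = value()))
    }
    if (identical(t, "between") && !peek_quoted()) {
      advance()
      v1 <- value(); expect("and"); v2 <- value()
      return(list(type = "cmp", op = "between", table = cr$table,
                  column = cr$column, values = c(v1, v2)))
    }
    opmap <- c("=" = "eq", "!=" = "ne", "<>" = "ne", ">" = "gt",
               ">=" = "ge", "<" = "lt", "<=" = "le", "like" = "like")
    if (is.null(t) || !(t %in% names(opmap)))
      medsql_error("medsql_syntax_error",
                   sprintf("expected a comparison operator near token %d", pos))
    op <- opmap[[advance()$text |> tolower()]]
    list(type = "cmp", op = op, table = cr$table, column = cr$column,
         values = value())
  }
  fold_right <- function(conn, parts) {
    out <- parts[[length(parts)]]
    for (i in rev(seq_len(length(parts) - 1L)))
      out <- list(type = "conn", conn = conn, left = parts[[i]], right = out)
    out
  }
  cond_and <- function() {
    parts <- list(cond_prim())
    while (identical(peek(), "and") && !peek_quoted()) {
      advance()
      parts[[length(parts) + 1L]] <- cond_prim()
    }
    fold_right("and", parts)
  }
  cond_or <- function() {
    parts <- list(cond_and())
    while (identical(peek(), "or") && !peek_quoted()) {
      advance()
      parts[[length(parts) + 1L]] <- cond_and()
    }
    fold_right("or", parts)
  }

  expect("select")
  items <- list(select_item())
  while (identical(peek(), ",") && !peek_quoted()) {
    advance()
    check_unsupported()
    items[[length(items) + 1L]] <- select_item()
  }
  expect("from")
  from_tables <- tolower(advance()$text)
  joins <- list()
  while (identical(peek(), "inner") && !peek_quoted()) {
    advance(); expect("join")
    jt <- tolower(advance()$text)
    expect("on")
    l <- colref(); expect("="); r <- colref()
    joins[[length(joins) + 1L]] <- list(table = jt, left = l, right = r)
    from_tables <- c(from_tables, jt)
  }
  where <- NULL
  check_unsupported()
  if (identical(peek(), "where") && !peek_quoted()) {
    advance()
    where <- cond_or()
  }
  check_unsupported()
  if (pos <= nrow(tk))
    medsql_error("medsql_syntax_error",
                 sprintf("unexpected trailing token '%s'", peek()))
  list(select = items, from = from_tables, joins = joins, where = where)
}

#' Parse SQL into an IR tree
#'
#' Accepts the engine's query subset (select with up to three items,
#' aggregates including `count(distinct ...)`, inner joins, and a Where
#' clause of and/or-connected comparisons). Any other construct raises
#' `medsql_unsupported_error` naming it. The From clause is syntax-checked
#' but not stored: it is re-derived from the tree's table leaves at render
#' time.
#'
#' @param sql SQL text.
#' @param schema A `medsql_schema`.
#' @param grammar Production table.
#' @return An IR tree whose value leaves carry literal text.
#' @export
sql_to_tree <- function(sql, schema, grammar = sql_grammar()) {
  q <- parse_sql_query(sql)
  cols <- schema_columns(schema)
  tabs <- schema_tables(schema)
  a_node <- function(agg, table, column) {
    cid <- match(paste(table, column, sep = "."), cols$qualified)
    if (is.na(cid))
      medsql_error("medsql_lookup_error",
                   sprintf("unknown column '%s.%s'", table, column))
    tid <- match(table, tabs)
    ir_node("A", grammar_rule_id(grammar, "A", agg),
            list(ir_leaf_c(cid), ir_leaf_t(tid)))
  }
  if (length(q$select) > 3L)
    medsql_error("medsql_unsupported_error",
                 "unsupported SQL construct: more than 3 select items")
  sel_children <- lapply(q$select, function(it) a_node(it$agg, it$table, it$column))
  sel <- ir_node("Select",
                 grammar_rule_id(grammar, "Select", NA, n_children = length(sel_children)),
                 sel_children)
  build_filter <- function(cnd) {
    if (cnd$type == "conn") {
      ir_node("Filter", grammar_rule_id(grammar, "Filter", cnd$conn),
              list(build_filter(cnd$left), build_filter(cnd$right)))
    } else {
      ch <- list(a_node("none", cnd$table, cnd$column))
      for (v in cnd$values) ch[[length(ch) + 1L]] <- ir_leaf_v(text = v)
      ir_node("Filter", grammar_rule_id(grammar, "Filter", cnd$op), ch)
    }
  }
  r_children <- list(sel)
  if (!is.null(q$where)) r_children[[2L]] <- build_filter(q$where)
  r <- ir_node("R", grammar_rule_id(grammar, "R", NA, n_children = length(r_children)),
               r_children)
  ir_node("Z", grammar_rule_id(grammar, "Z"), list(r))
}

# Rendering ----------------------------------------------------------------

OP_RENDER <- c(eq = "=", ne = "!=", gt = ">", ge = ">=", lt = "<",
               le = "<=", like = "like", nlike = "not like")

#' Render an IR tree as SQL
#'
#' The select and where clauses follow the tree's child order; the From
#' clause connects all referenced tables by the shortest join-key path
#' through the schema (breadth-first, edges in declaration order, origin =
#' first referenced table), rendered as inner joins. Keywords are
#' lower-case; columns render as `table."column"` and values are
#' double-quoted.
#'
#' @param tree A complete IR tree.
#' @param schema A `medsql_schema`.
#' @param tokens Question tokens; required when value leaves carry spans.
#' @param grammar Production table.
#' @return List with `sql` (the text) and `query` (the structured form).
#' @export
tree_to_sql <- function(tree, schema, tokens = NULL, grammar = sql_grammar()) {
  cols <- schema_columns(schema)
  tabs <- schema_tables(schema)
  val_text <- function(v) {
    if (!is.null(v$text)) return(v$text)
    if (is.null(tokens))
      medsql_error("medsql_value_error",
                   "value leaf carries a token span but no tokens were given")
    detokenize(tokens[(v$start + 1L):(v$end + 1L)])
  }
  a_parts <- function(a) {
    tag <- grammar$tag[a$prod]
    list(agg = tag, table = cols$table[a$children[[1]]$col],
         column = cols$column[a$children[[1]]$col],
         tab_leaf = tabs[a$children[[2]]$tab])
  }
  render_item <- function(p) {
    base <- sprintf('%s."%s"', p$table, p$column)
    if (p$agg == "none") base
    else if (p$agg == "count_distinct") sprintf("count(distinct %s)", base)
    else sprintf("%s(%s)", p$agg, base)
  }
  prec <- function(node) {
    tag <- grammar$tag[node$prod]
    if (identical(tag, "or")) 1L else if (identical(tag, "and")) 2L else 3L
  }
  render_filter <- function(node) {
    tag <- grammar$tag[node$prod]
    if (tag %in% c("and", "or")) {
      l <- node$children[[1]]; r <- node$children[[2]]
      ls <- render_filter(l); rs <- render_filter(r)
      if (prec(l) <= prec(node)) ls <- paste0("(", ls, ")")
      if (prec(r) < prec(node)) rs <- paste0("(", rs, ")")
      paste(ls, tag, rs)
    } else if (tag == "between") {
      p <- a_parts(node$children[[1]])
      sprintf('%s."%s" between "%s" and "%s"', p$table, p$column,
              val_text(node$children[[2]]), val_text(node$children[[3]]))
    } else {
      p <- a_parts(node$children[[1]])
      sprintf('%s."%s" %s "%s"', p$table, p$column, OP_RENDER[[tag]],
              val_text(node$children[[2]]))
    }
  }

  r <- tree$children[[1]]
  sel <- r$children[[1]]
  sel_parts <- lapply(sel$children, a_parts)
  items <- vapply(sel_parts, render_item, character(1))

  # tables referenced anywhere in the tree, in first-appearance order
  referenced <- character()
  walk_t <- function(node) {
    if (node$sym == "T") {
      tn <- tabs[node$tab]
      if (!tn %in% referenced) referenced <<- c(referenced, tn)
    } else if (!is.null(node$children)) {
      for (ch in node$children) walk_t(ch)
    }
  }
  walk_t(tree)
  joins <- join_path(schema, referenced)
  from_txt <- joins$text

  where_txt <- NULL
  if (length(r$children) == 2L) where_txt <- render_filter(r$children[[2]])

  sql <- paste0("select ", paste(items, collapse = ", "), " from ", from_txt)
  if (!is.null(where_txt)) sql <- paste0(sql, " where ", where_txt)

  cond_struct <- NULL
  collect_conds <- function(node) {
    tag <- grammar$tag[node$prod]
    if (tag %in% c("and", "or")) {
      list(type = "conn", conn = tag,
           left = collect_conds(node$children[[1]]),
           right = collect_conds(node$children[[2]]))
    } else {
      p <- a_parts(node$children[[1]])
      vals <- vapply(node$children[-1], val_text, character(1))
      list(type = "cmp", op = tag, table = p$table, column = p$column,
           values = vals)
    }
  }
  if (length(r$children) == 2L) cond_struct <- collect_conds(r$children[[2]])
  list(sql = sql,
       query = list(select = sel_parts, tables = referenced,
                    joins = joins$edges, where = cond_struct))
}

# Shortest join path connecting the referenced tables: grow an included
# set from the first table, BFS per target with edges in declaration order.
#' @keywords internal
join_path <- function(schema, tables) {
  if (length(tables) == 0L)
    medsql_error("medsql_join_error", "no tables referenced")
  included <- tables[1]
  edges <- list()
  txt <- tables[1]
  for (target in tables[-1]) {
    if (target %in% included) next
    # BFS from the included set
    prev <- list()
    queue <- included
    found <- FALSE
    visited <- included
    while (length(queue) > 0L && !found) {
      cur <- queue[1]; queue <- queue[-1]
      for (i in seq_len(nrow(schema$joins))) {
        e <- schema$joins[i, ]
        nbr <- if (e$left == cur) e$right else if (e$right == cur) e$left else next
        if (nbr %in% visited) next
        visited <- c(visited, nbr)
        prev[[nbr]] <- list(from = cur, key = e$key)
        if (nbr == target) { found <- TRUE; break }
        queue <- c(queue, nbr)
      }
    }
    if (!found)
      medsql_error("medsql_join_error",
                   sprintf("table '%s' is not connectable through join keys", target))
    # reconstruct path edges from the included boundary to the target
    path <- list()
    node <- target
    while (!node %in% included) {
      p <- prev[[node]]
      path[[length(path) + 1L]] <- list(from = p$from, to = node, key = p$key)
      node <- p$from
    }
    for (e in rev(path)) {
      edges[[length(edges) + 1L]] <- e
      included <- c(included, e$to)
      txt <- paste0(txt, sprintf(" inner join %s on %s.%s = %s.%s",
                                 e$to, e$from, e$key, e$to, e$key))
    }
  }
  list(text = txt, edges = edges)
}
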