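# Evaluation metrics: logic-form accuracy (canonical token equality),
# execution accuracy (equal result tables on a populated database), and a
# five-component breakdown of the generated SQL.

#' Logic-form accuracy
#'
#' A prediction matches iff its canonical token sequence equals the gold
#' query's ([canonicalize_sql()]); order-sensitive everywhere, so swapped
#' select columns or join tables break the match.
#'
#' @param pred,gold Character vectors of SQL text, equal length.
#' @return List with `acc`, `n_match`, `n`.
#' @export
acc_lf <- function(pred, gold) {
  if (length(pred) != length(gold))
    medsql_error("medsql_input_error", "pred and gold must have equal length")
  m <- mapply(function(p, g) identical(canonicalize_sql(p), canonicalize_sql(g)),
              pred, gold, USE.NAMES = FALSE)
  list(acc = if (length(m)) mean(m) else NA_real_, n_match = sum(m), n = length(m))
}

#' Execution accuracy
#'
#' A prediction matches iff it executes without error and its result table
#' equals the gold query's result, with column order respected and rows
#' compared as order-insensitive multisets. A gold query that fails to
#' execute is a dataset error.
#'
#' @param pred,gold Character vectors of SQL text, equal length.
#' @param db A `medsql_db` populated fixture.
#' @return List with `acc`, `n_match`, `n`.
#' @export
acc_ex <- function(pred, gold, db) {
  if (length(pred) != length(gold))
    medsql_error("medsql_input_error", "pred and gold must have equal length")
  m <- logical(length(pred))
  for (i in seq_along(pred)) {
    rg <- tryCatch(execute_query(db, gold[i]), medsql_exec_error = function(e) e)
    if (inherits(rg, "condition"))
      medsql_error("medsql_input_error",
                   sprintf("gold query %d failed to execute: %s", i, conditionMessage(rg)))
    rp <- tryCatch(execute_query(db, pred[i]), medsql_exec_error = function(e) NULL)
    m[i] <- !is.null(rp) && results_equal(rp, rg)
  }
  list(acc = if (length(m)) mean(m) else NA_real_, n_match = sum(m), n = length(m))
}

# Extract the five comparable component collections from a parsed tree.
#' @keywords internal
sql_components <- function(sql, schema) {
  tree <- tryCatch(sql_to_tree(sql, schema), medsql_error = function(e) NULL)
  if (is.null(tree)) return(NULL)
  g <- sql_grammar()
  rendered <- tree_to_sql(tree, schema)
  sel <- rendered$query$select
  agg_op <- sort(vapply(sel, `[[`, character(1), "agg"))
  agg_col <- sort(unique(vapply(sel, function(p) paste(p$table, p$column, sep = "."),
                                character(1))))
  tables <- sort(rendered$query$tables)
  conds <- list()
  walk <- function(c0) {
    if (is.null(c0)) return(invisible())
    if (c0$type == "conn") { walk(c0$left); walk(c0$right) }
    else conds[[length(conds) + 1L]] <<- c0
  }
  walk(rendered$query$where)
  con_co <- sort(unique(vapply(conds, function(cn)
    paste(cn$table, cn$column, cn$op, sep = "|"), character(1))))
  con_val <- sort(unique(tolower(unlist(lapply(conds, `[[`, "values"))))) %||% character()
  list(agg_op = agg_op, agg_col = agg_col, table = tables,
       con_c_plus_o = con_co, con_val = con_val)
}

#' Component accuracy of generated SQL
#'
#' Breaks each query into five components — aggregation-operation multiset,
#' aggregation-column set, table set, (condition column, operator) pair
#' set, and condition-value set (case-folded) — and scores each as the
#' fraction of pairs whose collections agree exactly. An unparseable
#' prediction counts all five components as wrong for that pair.
#'
#' @param pred,gold Character vectors of SQL text, equal length.
#' @param schema A `medsql_schema`.
#' @return Named list of five accuracies.
#' @export
component_accuracy <- function(pred, gold, schema) {
  if (length(pred) != length(gold))
    medsql_error("medsql_input_error", "pred and gold must have equal length")
  comps <- c("agg_op", "agg_col", "table", "con_c_plus_o", "con_val")
  hits <- matrix(FALSE, nrow = length(pred), ncol = length(comps),
                 dimnames = list(NULL, comps))
  for (i in seq_along(pred)) {
    cg <- sql_components(gold[i], schema)
    if (is.null(cg))
      medsql_error("medsql_input_error", sprintf("gold query %d is unparseable", i))
    cp <- sql_components(pred[i], schema)
    if (is.null(cp)) next
    for (k in comps) hits[i, k] <- identical(cp[[k]], cg[[k]])
  }
  as.list(colMeans(hits))
}

#' Full evaluation report
#'
#' @param pred,gold Character vectors of SQL text.
#' @param db A `medsql_db` (execution accuracy); its schema drives the
#'   component breakdown.
#' @return A `medsql_report`: `n`, `n_lf`, `n_ex`, `acc_lf`, `acc_ex`, and
#'   `components`.
#' @export
evaluate_pairs <- function(pred, gold, db) {
  lf <- acc_lf(pred, gold)
  ex <- acc_ex(pred, gold, db)
  comp <- component_accuracy(pred, gold, db$schema)
  structure(list(n = lf$n, n_lf = lf$n_match, n_ex = ex$n_match,
                 acc_lf = lf$acc, acc_ex = ex$acc, components = comp),
            class = "medsql_report")
}

#' @export
print.medsql_report <- function(x, ...) {
  cat(sprintf("<medsql_report> n=%d  Acc_LF=%.3f  Acc_EX=%.3f\n",
              x$n, x$acc_lf, x$acc_ex))
  cat("  components:",
      paste(sprintf("%s=%.3f", names(x$components), unlist(x$components)),
            collapse = "  "), "\n")
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report A `medsql_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(n = report$n, acc_lf = report$acc_lf, acc_ex = report$acc_ex,
         components = report$components),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
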