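# Embedded SQLite database layer: fixture construction, query execution,
# and column-content lookup used by condition-value recovery.

#' Build a fixture database from schema and records
#'
#' Creates (or overwrites) a SQLite database file containing one table per
#' schema table. Text-kind values are lower-cased at load so that condition
#' values rendered from lower-cased question tokens match stored content;
#' numeric-kind values must be coercible to numbers.
#'
#' @param schema A `medsql_schema`.
#' @param records Named list mapping table names to data frames (columns
#'   must match the schema's column names for that table). Tables absent
#'   from `records` are created empty.
#' @param path Path for the SQLite file, or `":memory:"`.
#' @return A `medsql_db` handle (keep it; close with [close_db()]).
#' @export
build_fixture_db <- function(schema, records = list(), path = ":memory:") {
  if (path != ":memory:" && file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  for (t in schema$tables) {
    # text columns collate case-insensitively so condition values rendered
    # from lower-cased question tokens match stored content regardless of
    # the case a caller writes into a query
    decl <- paste(sprintf('"%s" %s', t$columns$name,
                          ifelse(t$columns$kind == "numeric", "NUMERIC",
                                 "TEXT COLLATE NOCASE")),
                  collapse = ", ")
    DBI::dbExecute(con, sprintf('create table "%s" (%s)', t$name, decl))
    rec <- records[[t$name]]
    if (!is.null(rec) && nrow(rec) > 0L) {
      if (!setequal(names(rec), t$columns$name))
        medsql_error("medsql_load_error",
                     sprintf("records for table '%s' do not match its columns", t$name))
      rec <- rec[, t$columns$name, drop = FALSE]
      for (i in seq_len(nrow(t$columns))) {
        cn <- t$columns$name[i]
        if (t$columns$kind[i] == "numeric") {
          v <- suppressWarnings(as.numeric(rec[[cn]]))
          if (anyNA(v) && !all(is.na(rec[[cn]]) == is.na(v)))
            medsql_error("medsql_load_error",
                         sprintf("non-numeric value in numeric column '%s.%s'",
                                 t$name, cn))
          rec[[cn]] <- v
        } else {
          rec[[cn]] <- tolower(as.character(rec[[cn]]))
        }
      }
      DBI::dbWriteTable(con, t$name, rec, append = TRUE)
    }
  }
  # stash the schema so the file is self-describing
  DBI::dbExecute(con, "create table _medsql_schema (yaml TEXT)")
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  write_schema(schema, tf)
  DBI::dbExecute(con, "insert into _medsql_schema values (:y)",
                 params = list(y = paste(readLines(tf), collapse = "\n")))
  structure(list(con = con, schema = schema, path = path), class = "medsql_db")
}

#' Open an existing fixture database
#'
#' @param path Path to a SQLite file created by [build_fixture_db()].
#' @return A `medsql_db` handle.
#' @export
open_db <- function(path) {
  if (!file.exists(path))
    medsql_error("medsql_lookup_error", sprintf("database file not found: %s", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  ytxt <- tryCatch(DBI::dbGetQuery(con, "select yaml from _medsql_schema")$yaml[1],
                   error = function(e) NA_character_)
  if (is.na(ytxt)) {
    DBI::dbDisconnect(con)
    medsql_error("medsql_lookup_error", "file carries no embedded schema")
  }
  tf <- tempfile(fileext = ".yaml")
  writeLines(ytxt, tf)
  on.exit(unlink(tf), add = TRUE)
  schema <- load_schema(tf)
  structure(list(con = con, schema = schema, path = path), class = "medsql_db")
}

#' Close a database handle
#' @param db A `medsql_db`.
#' @export
close_db <- function(db) {
  DBI::dbDisconnect(db$con)
  invisible(NULL)
}

#' Execute a SQL query on a fixture database
#'
#' Runs the query through the SQLite engine. Engine-level failures
#' (malformed SQL, unknown identifiers) are signalled as a classed
#' condition `medsql_exec_error` rather than an unstructured crash, so
#' callers such as [acc_ex()] can count them as non-executable.
#'
#' @param db A `medsql_db`.
#' @param sql SQL text.
#' @return A `medsql_result`: list with `column_labels` (in select-clause
#'   order) and `rows` (list of value tuples).
#' @export
execute_query <- function(db, sql) {
  df <- tryCatch(DBI::dbGetQuery(db$con, sql), error = function(e) {
    medsql_error("medsql_exec_error",
                 sprintf("query failed to execute: %s", conditionMessage(e)))
  })
  rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  structure(list(column_labels = names(df), rows = unname(rows)),
            class = "medsql_result")
}

# Order-insensitive row comparison with column order respected; labels are
# presentation (they echo the query text) and are not compared.
#' Compare two execution results
#'
#' Rows are compared as multisets (the query subset has no ORDER BY);
#' column order within a row is significant.
#'
#' @param a,b `medsql_result` objects.
#' @return Logical scalar.
#' @export
results_equal <- function(a, b) {
  if (length(a$column_labels) != length(b$column_labels)) return(FALSE)
  key <- function(r) {
    vapply(r, function(tup) paste(vapply(tup, format_cell, character(1)),
                                  collapse = "\x1f"), character(1))
  }
  ka <- sort(key(a$rows))
  kb <- sort(key(b$rows))
  length(ka) == length(kb) && all(ka == kb)
}

#' @keywords internal
format_cell <- function(v) {
  if (is.null(v) || (length(v) == 1L && is.na(v))) return("<NA>")
  if (is.numeric(v)) return(format(v, digits = 15))
  as.character(v)
}

#' Distinct stored values of a column
#'
#' Returns the distinct values in first-seen (insertion) order, for use as
#' the candidate pool of condition-value recovery.
#'
#' @param db A `medsql_db`.
#' @param table,column Identifiers naming a schema column.
#' @return Character (or numeric) vector of distinct values.
#' @export
lookup_values <- function(db, table, column) {
  column_kind(db$schema, table, column)  # validates existence
  v <- DBI::dbGetQuery(db$con,
                       sprintf('select "%s" from "%s"', column, table))[[1]]
  v <- v[!is.na(v)]
  v[!duplicated(v)]
}
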