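# Relational schema model: tables, typed columns, and the join-key graph
# over which From clauses are constructed.

#' Construct a database schema object
#'
#' A schema is an ordered list of tables, each with ordered, typed columns,
#' plus a join graph given as (left table, right table, key column) edges.
#' The join graph must be connected and every key must exist in both
#' endpoint tables.
#'
#' @param tables List of tables. Each table is a list with elements `name`
#'   (string) and `columns`, a data frame with columns `name`, `kind`
#'   (`"text"` or `"numeric"`) and `join_key` (logical).
#' @param joins Data frame with columns `left`, `right`, `key` (possibly
#'   zero rows).
#' @return An object of class `medsql_schema`.
#' @export
medsql_schema <- function(tables, joins = NULL) {
  if (is.null(joins)) {
    joins <- data.frame(left = character(), right = character(),
                        key = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.list(tables), length(tables) >= 1L)
  tnames <- vapply(tables, function(t) t$name, character(1))
  if (anyDuplicated(tnames))
    medsql_error("medsql_schema_error", "duplicate table names in schema")
  for (t in tables) {
    cols <- t$columns
    if (!is.data.frame(cols) || nrow(cols) < 1L)
      medsql_error("medsql_schema_error",
                   sprintf("table '%s' has no columns", t$name))
    if (!all(c("name", "kind") %in% names(cols)))
      medsql_error("medsql_schema_error",
                   sprintf("table '%s': columns need 'name' and 'kind'", t$name))
    if (anyDuplicated(cols$name))
      medsql_error("medsql_schema_error",
                   sprintf("duplicate column name in table '%s'", t$name))
    if (!all(cols$kind %in% c("text", "numeric")))
      medsql_error("medsql_schema_error",
                   sprintf("table '%s': kind must be 'text' or 'numeric'", t$name))
    if (any(!nzchar(cols$name)))
      medsql_error("medsql_schema_error",
                   sprintf("table '%s': empty column name", t$name))
  }
  names(tables) <- tnames
  for (i in seq_len(nrow(joins))) {
    e <- joins[i, ]
    for (side in c(e$left, e$right)) {
      if (!side %in% tnames)
        medsql_error("medsql_schema_error",
                     sprintf("join edge references unknown table '%s'", side))
      if (!e$key %in% tables[[side]]$columns$name)
        medsql_error("medsql_schema_error",
                     sprintf("join key '%s' missing from table '%s'", e$key, side))
    }
  }
  sch <- structure(list(tables = tables, joins = joins),
                   class = "medsql_schema")
  if (!schema_connected(sch))
    medsql_error("medsql_schema_error", "join graph over tables is not connected")
  sch
}

#' @keywords internal
schema_connected <- function(schema) {
  tnames <- names(schema$tables)
  if (length(tnames) <= 1L) return(TRUE)
  seen <- tnames[1]
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(schema$joins))) {
      e <- schema$joins[i, ]
      if (e$left %in% seen && !(e$right %in% seen)) { seen <- c(seen, e$right); grew <- TRUE }
      if (e$right %in% seen && !(e$left %in% seen)) { seen <- c(seen, e$left); grew <- TRUE }
    }
    if (!grew) break
  }
  length(seen) == length(tnames)
}

#' Load a schema from a YAML or JSON config file
#'
#' The config has keys `tables[].name`, `tables[].columns[].{name,kind,join_key}`
#' and `joins[].{left,right,key}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `medsql_schema`.
#' @export
load_schema <- function(path) {
  if (!file.exists(path))
    medsql_error("medsql_parse_error", sprintf("schema file not found: %s", path))
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    medsql_error("medsql_parse_error",
                 sprintf("malformed schema file '%s': %s", path, conditionMessage(e)))
  })
  if (is.null(raw$tables))
    medsql_error("medsql_parse_error", "schema file has no 'tables' entry")
  tables <- lapply(raw$tables, function(t) {
    if (is.null(t$name))
      medsql_error("medsql_parse_error", "a table entry is missing 'name'")
    cols <- do.call(rbind, lapply(t$columns, function(cl) {
      if (is.null(cl$name))
        medsql_error("medsql_parse_error",
                     sprintf("table '%s': a column entry is missing 'name'", t$name))
      data.frame(name = cl$name, kind = cl$kind %||% "text",
                 join_key = isTRUE(cl$join_key), stringsAsFactors = FALSE)
    }))
    list(name = t$name, columns = cols)
  })
  joins <- if (length(raw$joins)) {
    do.call(rbind, lapply(raw$joins, function(j) {
      data.frame(left = j$left, right = j$right, key = j$key,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  medsql_schema(tables, joins)
}

#' Write a schema to a YAML config file
#'
#' @param schema A `medsql_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  out <- list(
    tables = lapply(schema$tables, function(t) {
      list(name = t$name, columns = lapply(seq_len(nrow(t$columns)), function(i) {
        list(name = t$columns$name[i], kind = t$columns$kind[i],
             join_key = t$columns$join_key[i])
      }))
    }),
    joins = lapply(seq_len(nrow(schema$joins)), function(i) {
      as.list(schema$joins[i, ])
    })
  )
  names(out$tables) <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Enumerate the column universe of a schema
#'
#' Returns one row per schema-qualified column, in table-then-declaration
#' order. The row index is the column id used by `SelectColumn` actions.
#'
#' @param schema A `medsql_schema`.
#' @return Data frame with columns `id`, `table`, `column`, `kind`,
#'   `join_key`, `qualified`.
#' @export
schema_columns <- function(schema) {
  schema_memo(schema, "columns", function() {
    rows <- lapply(schema$tables, function(t) {
      data.frame(table = t$name, column = t$columns$name, kind = t$columns$kind,
                 join_key = t$columns$join_key, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df$id <- seq_len(nrow(df))
    df$qualified <- paste(df$table, df$column, sep = ".")
    df[, c("id", "table", "column", "kind", "join_key", "qualified")]
  })
}

#' Table names of a schema, in declaration order
#'
#' The row index is the table id used by `SelectTable` actions.
#'
#' @param schema A `medsql_schema`.
#' @return Character vector.
#' @export
schema_tables <- function(schema) {
  unname(names(schema$tables))
}

#' @keywords internal
column_kind <- function(schema, table, column) {
  t <- schema$tables[[table]]
  if (is.null(t))
    medsql_error("medsql_lookup_error", sprintf("unknown table '%s'", table))
  i <- match(column, t$columns$name)
  if (is.na(i))
    medsql_error("medsql_lookup_error",
                 sprintf("unknown column '%s.%s'", table, column))
  t$columns$kind[i]
}

#' @export
print.medsql_schema <- function(x, ...) {
  cat("<medsql_schema> ", length(x$tables), " tables: ",
      paste(sprintf("%s(%d)", names(x$tables),
                    vapply(x$tables, function(t) nrow(t$columns), integer(1))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
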