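# Schema linking: longest-first n-gram matching of question tokens against
# column and table names. Matched n-grams become single spans carrying a
# COLUMN or TABLE mark; everything else becomes one single-token NONE span.

#' Link question tokens to schema entities
#'
#' Enumerates all n-grams (n from 5 down to 1, left-to-right within a
#' length). An n-gram that exactly matches a column name, or whose word
#' set is a subset of a column name's word set (names are lower-cased and
#' underscore-split), is marked COLUMN; likewise TABLE for table names. A
#' double match takes the COLUMN mark (higher priority). Once a span is
#' fixed, overlapping candidates are discarded. Among several matching
#' entities an exact full-name match beats a subset match, then schema
#' declaration order decides.
#'
#' @param tokens Tokens from [tokenize_question()].
#' @param schema A `medsql_schema`.
#' @return A `medsql_marked` object: list with `tokens` and `spans`, each
#'   span holding `tokens`, `mark` (`"COLUMN"`, `"TABLE"`, `"NONE"`),
#'   `entity` (qualified column / table name or `NA`), and 1-based
#'   inclusive token positions `from`, `to`.
#' @export
link_schema <- function(tokens, schema) {
  cols <- schema_columns(schema)
  mt <- schema_memo(schema, "linker", function() {
    col_words <- lapply(cols$column, name_words)
    tab_words <- lapply(schema_tables(schema), name_words)
    list(col_words = col_words, tab_words = tab_words,
         # an n-gram can only match if every word occurs in some schema name
         word_set = unique(c(unlist(col_words), unlist(tab_words))))
  })
  col_words <- mt$col_words
  tab_names <- schema_tables(schema)
  tab_words <- mt$tab_words
  schema_word_set <- mt$word_set

  match_entity <- function(gram) {
    gram_set <- unique(gram)
    exact_col <- which(vapply(col_words, function(w) identical(w, gram), logical(1)))
    if (length(exact_col)) return(list(mark = "COLUMN", entity = cols$qualified[exact_col[1]]))
    sub_col <- which(vapply(col_words, function(w) all(gram_set %in% w), logical(1)))
    exact_tab <- which(vapply(tab_words, function(w) identical(w, gram), logical(1)))
    sub_tab <- which(vapply(tab_words, function(w) all(gram_set %in% w), logical(1)))
    # column beats table at equal evidence strength; exact beats subset
    if (length(sub_col)) return(list(mark = "COLUMN", entity = cols$qualified[sub_col[1]]))
    if (length(exact_tab)) return(list(mark = "TABLE", entity = tab_names[exact_tab[1]]))
    if (length(sub_tab)) return(list(mark = "TABLE", entity = tab_names[sub_tab[1]]))
    NULL
  }

  n_tok <- length(tokens)
  taken <- rep(FALSE, n_tok)
  fixed <- list()
  low <- tolower(tokens)
  for (n in rev(seq_len(min(5L, n_tok)))) {
    if (n_tok < n) next
    for (s in seq_len(n_tok - n + 1L)) {
      idx <- s:(s + n - 1L)
      if (any(taken[idx])) next
      gram <- low[idx]
      if (!all(gram %in% schema_word_set)) next
      if (any(grepl("^[[:punct:]]+$", gram))) next
      hit <- match_entity(gram)
      if (!is.null(hit)) {
        taken[idx] <- TRUE
        fixed[[length(fixed) + 1L]] <- list(from = s, to = s + n - 1L,
                                            mark = hit$mark, entity = hit$entity)
      }
    }
  }
  spans <- list()
  i <- 1L
  starts <- vapply(fixed, `[[`, integer(1), "from")
  while (i <= n_tok) {
    j <- match(i, starts)
    if (!is.na(j)) {
      f <- fixed[[j]]
      spans[[length(spans) + 1L]] <- list(tokens = tokens[f$from:f$to],
                                          mark = f$mark, entity = f$entity,
                                          from = f$from, to = f$to)
      i <- f$to + 1L
    } else {
      spans[[length(spans) + 1L]] <- list(tokens = tokens[i], mark = "NONE",
                                          entity = NA_character_, from = i, to = i)
      i <- i + 1L
    }
  }
  structure(list(tokens = tokens, spans = spans), class = "medsql_marked")
}

#' @export
print.medsql_marked <- function(x, ...) {
  for (s in x$spans) {
    lab <- if (s$mark == "NONE") "" else sprintf(" [%s %s]", s$mark, s$entity)
    cat(paste(s$tokens, collapse = " "), lab, "\n", sep = "")
  }
  invisible(x)
}

#' Dump a marked question as JSON
#' @param mq A `medsql_marked`.
#' @return JSON string.
#' @export
marked_to_json <- function(mq) {
  jsonlite::toJSON(list(tokens = mq$tokens, spans = mq$spans), auto_unbox = TRUE)
}
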