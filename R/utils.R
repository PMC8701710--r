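#' @keywords internal
#' @useDynLib medsql, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Word-level tokenizer shared by question processing, ROUGE scoring and
# schema-name normalization. Lower-cases, straightens typographic quotes,
# and splits punctuation off as separate tokens.
#' Tokenize a natural-language question
#'
#' Lower-cases the text and splits it into word tokens, separating
#' punctuation (including `/`, used inside ethnicity values) into its own
#' tokens. Deterministic; an empty string yields an empty character vector.
#'
#' @param text Character scalar.
#' @return Character vector of tokens.
#' @examples
#' tokenize_question("Tell me the insurance of James Sloan.")
#' @export
tokenize_question <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- gsub("[“”]", "\"", x)
  x <- gsub("[‘’]", "'", x)
  # split off punctuation marks as standalone tokens
  x <- gsub("([.,;:?!()\"'/])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Inverse of tokenize_question for value spans: rejoins tokens with spaces,
# reattaching `/` tightly so stored values like "american indian/alaska
# native" round-trip through the tokenizer.
#' @keywords internal
detokenize <- function(tokens) {
  if (length(tokens) == 0L) return("")
  s <- paste(tokens, collapse = " ")
  s <- gsub(" / ", "/", s, fixed = TRUE)
  s <- gsub(" ([.,;:?!])", "\\1", s)
  s
}

# Normalize an identifier (column/table name) into its word sequence:
# lower-case, underscores become spaces.
#' @keywords internal
name_words <- function(name) {
  strsplit(tolower(gsub("_", " ", name)), "\\s+")[[1]]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-local memoisation for schema-derived lookup structures. Keys are
# built from the schema's content, so mutated copies never see stale data.
.medsql_cache <- new.env(parent = emptyenv())

#' @keywords internal
schema_key <- function(schema) {
  paste(vapply(schema$tables, function(t)
    paste(t$name, paste(t$columns$name, collapse = ","),
          paste(t$columns$kind, collapse = ","), sep = ":"),
    character(1)), collapse = ";")
}

#' @keywords internal
schema_memo <- function(schema, what, build) {
  key <- paste0(what, "\r", schema_key(schema))
  hit <- .medsql_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- build()
  .medsql_cache[[key]] <- val
  val
}

# Classed conditions -------------------------------------------------------

#' @keywords internal
medsql_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "medsql_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
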