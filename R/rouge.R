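# ROUGE-L similarity and condition-value recovery: a decoder-extracted
# value string is snapped to the most similar value actually stored in the
# database column, so rendered conditions match stored content.

#' ROUGE-L F-measure between two token sequences
#'
#' Longest-common-subsequence recall and precision combined with equal
#' weighting (F1). Returns 1 for identical nonempty sequences, 0 when the
#' LCS is empty (including when either side is empty); symmetric.
#'
#' @param a,b Character vectors of tokens.
#' @return Numeric scalar in `[0, 1]`.
#' @export
rouge_l <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0)
  # dynamic-programming LCS length
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  lcs <- prev[nb + 1L]
  if (lcs == 0L) return(0)
  p <- lcs / na
  r <- lcs / nb
  2 * p * r / (p + r)
}

#' Recover a condition value against database content
#'
#' For a text-kind column, returns the stored value most similar to the
#' extracted string by ROUGE-L over lower-cased word tokens; an exact
#' case-insensitive match short-circuits, and ties break to the first
#' candidate in stable lookup order. Numeric-kind values pass through
#' verbatim (numbers must not be snapped to unrelated stored numbers).
#' When the column holds no values the input is returned unchanged with a
#' `medsql_recovery_warning`.
#'
#' @param extracted The value string extracted from the question.
#' @param db A `medsql_db`.
#' @param table,column Identifiers of the condition column.
#' @return A stored value, or `extracted` unchanged.
#' @export
recover_value <- function(extracted, db, table, column) {
  kind <- column_kind(db$schema, table, column)
  if (kind == "numeric") return(extracted)
  cands <- lookup_values(db, table, column)
  if (length(cands) == 0L) {
    warning(structure(
      class = c("medsql_recovery_warning", "warning", "condition"),
      list(message = sprintf("column %s.%s holds no values; keeping '%s'",
                             table, column, extracted), call = NULL)))
    return(extracted)
  }
  cands <- as.character(cands)
  exact <- which(tolower(cands) == tolower(extracted))
  if (length(exact)) return(cands[exact[1]])
  et <- tokenize_question(extracted)
  scores <- vapply(cands, function(cd) rouge_l(et, tokenize_question(cd)),
                   numeric(1), USE.NAMES = FALSE)
  cands[which.max(scores)]
}
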