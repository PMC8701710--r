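# Shared fixtures, built once per test run. Sizes are kept small so the
# whole suite stays fast; the acceptance tests build their own larger
# corpora.

.fx <- new.env(parent = emptyenv())

fx_schema <- function() {
  if (is.null(.fx$schema)) .fx$schema <- make_schema()
  .fx$schema
}

# A small generated corpus + fixture database (200 pairs, 60 patients).
fx_gen <- function() {
  if (is.null(.fx$gen)) {
    sch <- fx_schema()
    rec <- sample_records(sch, 60, seed = 101)
    .fx$gen <- generate_pairs(sch, rec, gen_config(n_pairs = 200,
                                                   n_patients = 60,
                                                   seed = 101))
  }
  .fx$gen
}

# A tiny two-table schema for focused linking / grammar tests.
fx_tiny_schema <- function() {
  medsql_schema(
    tables = list(
      list(name = "people", columns = data.frame(
        name = c("person_id", "full_name", "insurance", "days_stay"),
        kind = c("numeric", "text", "text", "numeric"),
        join_key = c(FALSE, FALSE, FALSE, FALSE))),
      list(name = "visits", columns = data.frame(
        name = c("person_id", "reason"),
        kind = c("numeric", "text"),
        join_key = c(TRUE, FALSE)))),
    joins = data.frame(left = "people", right = "visits", key = "person_id"))
}

# Seeded random grammar-valid tree generator. Produces index-form value
# leaves together with a synthetic token list in which every value span
# is present, so both round trips (actions and SQL) can be exercised.
random_tree_case <- function(schema, grammar = sql_grammar(), max_cond_depth = 2L) {
  cols <- schema_columns(schema)
  tabs <- schema_tables(schema)
  aggs <- c("none", "max", "min", "count", "sum", "avg", "count_distinct")
  ops <- c("eq", "ne", "gt", "ge", "lt", "le", "like", "nlike")
  tokens <- c("q0")
  rid <- function(lhs, tag = NA, n = NULL) {
    hit <- grammar$lhs == lhs &
      (is.na(tag) & is.na(grammar$tag) |
         !is.na(tag) & !is.na(grammar$tag) & grammar$tag == tag)
    if (!is.null(n)) hit <- hit & lengths(grammar$rhs) == n
    grammar$id[hit]
  }
  mk_a <- function(agg) {
    ci <- sample(nrow(cols), 1)
    list(sym = "A", prod = rid("A", agg),
         children = list(list(sym = "C", col = as.integer(ci)),
                         list(sym = "T",
                              tab = match(cols$table[ci], tabs))))
  }
  mk_v <- function() {
    # add 1-2 fresh value tokens to the synthetic question
    k <- sample(1:2, 1)
    start <- length(tokens)
    tokens <<- c(tokens, sprintf("v%d_%d", start, seq_len(k)))
    list(sym = "V", start = start, end = start + k - 1L)
  }
  mk_filter <- function(depth) {
    if (depth < max_cond_depth && stats::runif(1) < 0.3) {
      conn <- sample(c("and", "or"), 1)
      list(sym = "Filter", prod = rid("Filter", conn),
           children = list(mk_filter(depth + 1L), mk_filter(depth + 1L)))
    } else if (stats::runif(1) < 0.12) {
      list(sym = "Filter", prod = rid("Filter", "between"),
           children = list(mk_a("none"), mk_v(), mk_v()))
    } else {
      op <- sample(ops, 1)
      list(sym = "Filter", prod = rid("Filter", op),
           children = list(mk_a("none"), mk_v()))
    }
  }
  n_sel <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
  sel <- list(sym = "Select", prod = rid("Select", NA, n = n_sel),
              children = lapply(seq_len(n_sel),
                                function(i) mk_a(sample(aggs, 1))))
  has_filter <- stats::runif(1) < 0.75
  r_children <- list(sel)
  if (has_filter) r_children[[2]] <- mk_filter(1L)
  r <- list(sym = "R", prod = rid("R", NA, n = length(r_children)),
            children = r_children)
  tree <- list(sym = "Z", prod = rid("Z"), children = list(r))
  list(tree = tree, tokens = tokens)
}

# Convert an index-form tree to text-form (value leaves carry literal
# text), for SQL round-trip checks.
tree_with_text_values <- function(tree, tokens) {
  walk <- function(node) {
    if (node$sym == "V") {
      txt <- paste(tokens[(node$start + 1L):(node$end + 1L)], collapse = " ")
      return(list(sym = "V", text = txt))
    }
    if (!is.null(node$children)) node$children <- lapply(node$children, walk)
    node
  }
  walk(tree)
}
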