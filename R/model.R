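# Model container: configuration, vocabulary, input serialization, the
# self-attention encoder over question + schema, and decoder
# initialization from the [CLS] representation.

#' Model configuration
#'
#' Desk-scale defaults train a small self-attention encoder from scratch
#' jointly with the decoder; the encoder backend contract is any map from
#' the serialized token stream to per-position hidden vectors, so a
#' pretrained bidirectional transformer (width 768, decoder 300) can be
#' substituted where its weights are available.
#'
#' @param enc_dim Encoder width (hidden size per position).
#' @param enc_layers Number of self-attention layers.
#' @param enc_heads Attention heads per layer.
#' @param dec_dim Decoder LSTM hidden size.
#' @param max_actions Maximum action-sequence length.
#' @param max_pos Maximum serialized stream length (positional table size).
#' @return A `medsql_config` list.
#' @export
model_config <- function(enc_dim = 48L, enc_layers = 2L, enc_heads = 2L,
                         dec_dim = 96L, max_actions = 128L, max_pos = 320L) {
  stopifnot(enc_dim %% enc_heads == 0L)
  structure(list(enc_dim = as.integer(enc_dim),
                 enc_layers = as.integer(enc_layers),
                 enc_heads = as.integer(enc_heads),
                 dec_dim = as.integer(dec_dim),
                 max_actions = as.integer(max_actions),
                 max_pos = as.integer(max_pos)),
            class = "medsql_config")
}

SPECIALS <- c("[cls]", "[sep]", "[unk]", "[num]", "[mcol]", "[mtab]", "[mnone]")

#' Build a vocabulary from training questions and the schema
#'
#' All-digit tokens map to a shared `[num]` symbol; unseen tokens at
#' inference time map to `[unk]`. Schema name words are always included.
#'
#' @param examples Corpus examples (only their `tokens` are used).
#' @param schema A `medsql_schema`.
#' @return Character vector of vocabulary items.
#' @export
build_vocab <- function(examples, schema) {
  toks <- unlist(lapply(examples, `[[`, "tokens"))
  cols <- schema_columns(schema)
  schema_words <- c(unlist(lapply(cols$column, name_words)),
                    unlist(lapply(schema_tables(schema), name_words)))
  toks <- c(toks, schema_words)
  toks <- tolower(toks)
  toks[grepl("^[0-9]+$", toks)] <- "[num]"
  unique(c(SPECIALS, sort(unique(toks))))
}

#' @keywords internal
vocab_ids <- function(tokens, vocab) {
  t <- tolower(tokens)
  t[grepl("^[0-9]+$", t)] <- "[num]"
  i <- match(t, vocab)
  i[is.na(i)] <- match("[unk]", vocab)
  i
}

#' Serialize a marked question and schema into the encoder token stream
#'
#' Layout: `[cls]`, then each question span's words followed by its mark
#' token (`[mcol]`, `[mtab]` or `[mnone]`), `[sep]`, each column's name
#' words followed by `[sep]`, then each table's name words followed by
#' `[sep]`. Span, column and table positions are recorded so their hidden
#' vectors can be average-pooled.
#'
#' Position ids run sequentially through the question block but restart
#' inside every column/table block, and each block carries a segment id
#' (question, or the table it belongs to). Self-attention is otherwise
#' order-free, so encodings of columns are equivariant under reordering
#' columns within a table, while same-named columns of different tables
#' stay distinguishable through their segment.
#'
#' @param mq A `medsql_marked` question.
#' @param schema A `medsql_schema`.
#' @return A `medsql_stream`: `tokens`, `pos_ids`, `seg_ids`, `q_spans`
#'   (positions + token range per span), `col_pos`, `tab_pos`, `cls_pos`.
#' @export
serialize_input <- function(mq, schema) {
  marks <- c(COLUMN = "[mcol]", TABLE = "[mtab]", NONE = "[mnone]")
  tabs <- schema_tables(schema)
  tokens <- "[cls]"
  pos_ids <- 1L
  seg_ids <- 1L
  q_spans <- list()
  for (s in mq$spans) {
    pos <- length(tokens) + seq_len(length(s$tokens) + 1L)
    tokens <- c(tokens, s$tokens, marks[[s$mark]])
    pos_ids <- c(pos_ids, max(pos_ids) + seq_along(pos))
    seg_ids <- c(seg_ids, rep(1L, length(pos)))
    q_spans[[length(q_spans) + 1L]] <- list(pos = pos, from = s$from, to = s$to)
  }
  tokens <- c(tokens, "[sep]")
  pos_ids <- c(pos_ids, max(pos_ids) + 1L)
  seg_ids <- c(seg_ids, 1L)
  # the schema block is question-independent; build it once per schema
  sb <- schema_memo(schema, "stream_block", function() {
    cols <- schema_columns(schema)
    b_tokens <- character(); b_pos <- integer(); b_seg <- integer()
    col_pos <- vector("list", nrow(cols))
    for (i in seq_len(nrow(cols))) {
      w <- name_words(cols$column[i])
      col_pos[[i]] <- length(b_tokens) + seq_along(w)
      b_tokens <- c(b_tokens, w, "[sep]")
      b_pos <- c(b_pos, seq_len(length(w) + 1L))
      b_seg <- c(b_seg, rep(1L + match(cols$table[i], tabs), length(w) + 1L))
    }
    tab_pos <- vector("list", length(tabs))
    for (i in seq_along(tabs)) {
      w <- name_words(tabs[i])
      tab_pos[[i]] <- length(b_tokens) + seq_along(w)
      b_tokens <- c(b_tokens, w, "[sep]")
      b_pos <- c(b_pos, seq_len(length(w) + 1L))
      b_seg <- c(b_seg, rep(1L + i, length(w) + 1L))
    }
    list(tokens = b_tokens, pos = b_pos, seg = b_seg,
         col_pos = col_pos, tab_pos = tab_pos)
  })
  off <- length(tokens)
  structure(list(tokens = c(tokens, sb$tokens),
                 pos_ids = c(pos_ids, sb$pos),
                 seg_ids = c(seg_ids, sb$seg),
                 q_spans = q_spans,
                 col_pos = lapply(sb$col_pos, `+`, off),
                 tab_pos = lapply(sb$tab_pos, `+`, off),
                 cls_pos = 1L),
            class = "medsql_stream")
}

# Parameter initialization --------------------------------------------------

#' @keywords internal
xavier <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize model parameters
#'
#' @param vocab Vocabulary from [build_vocab()].
#' @param schema A `medsql_schema`.
#' @param config A [model_config()].
#' @param seed Integer seed for the random initialization.
#' @return A `medsql_model`: list with `params`, `config`, `vocab`, and a
#'   `grammar` fingerprint (the production table itself).
#' @export
medsql_model <- function(vocab, schema, config = model_config(), seed = 1L) {
  set.seed(seed)
  D <- config$enc_dim; Hd <- config$dec_dim; F_ <- 2L * D
  n_rules <- nrow(sql_grammar())
  P <- list(
    Etok = xavier(length(vocab), D),
    Epos = xavier(config$max_pos, D),
    Eseg = xavier(1L + length(schema_tables(schema)), D),
    Wpool = xavier(D, D), bpool = numeric(D),
    Wcls = xavier(Hd, D), bcls = numeric(Hd),
    Erule = xavier(n_rules, D), estart = stats::rnorm(D, sd = 0.1),
    lstm_Wx = xavier(4L * Hd, D), lstm_Wh = xavier(4L * Hd, Hd),
    lstm_b = numeric(4L * Hd),
    Wax = xavier(D, Hd), Wac = xavier(D, Hd),
    Wr = xavier(n_rules, Hd + 2L * D), br = numeric(n_rules),
    Wsch = xavier(D, Hd + D), Wmem = xavier(D, Hd + D),
    Wtab = xavier(D, Hd + D), Wvs = xavier(D, Hd + D),
    Wve = xavier(D, Hd + 2L * D),
    wg = stats::rnorm(Hd + D, sd = 0.05), bg = 0
  )
  for (l in seq_len(config$enc_layers)) {
    P[[paste0("l", l, "_Wq")]] <- xavier(D, D)
    P[[paste0("l", l, "_Wk")]] <- xavier(D, D)
    P[[paste0("l", l, "_Wv")]] <- xavier(D, D)
    P[[paste0("l", l, "_Wo")]] <- xavier(D, D)
    P[[paste0("l", l, "_g1")]] <- rep(1, D)
    P[[paste0("l", l, "_b1")]] <- numeric(D)
    P[[paste0("l", l, "_W1")]] <- xavier(D, F_)
    P[[paste0("l", l, "_bf1")]] <- numeric(F_)
    P[[paste0("l", l, "_W2")]] <- xavier(F_, D)
    P[[paste0("l", l, "_bf2")]] <- numeric(D)
    P[[paste0("l", l, "_g2")]] <- rep(1, D)
    P[[paste0("l", l, "_b2")]] <- numeric(D)
  }
  structure(list(params = P, config = config, vocab = vocab,
                 grammar = sql_grammar(), schema_tables = schema_tables(schema),
                 n_columns = nrow(schema_columns(schema))),
            class = "medsql_model")
}

# Encoder forward/backward --------------------------------------------------

#' Encode a serialized stream into span, column and table vectors
#'
#' Self-attention layers over the whole stream, then average pooling of
#' each span's word-and-mark positions (each column's and table's word
#' positions) through a shared fully connected tanh pooling layer.
#' Deterministic given parameters.
#'
#' @param stream A `medsql_stream` from [serialize_input()].
#' @param model A `medsql_model`.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return A `medsql_encodings`: `H_X` (spans x width), `H_C`, `H_T`,
#'   `h_cls`, `width`, and (optionally) `cache`.
#' @export
encode <- function(stream, model, keep_cache = FALSE) {
  P <- model$params; cfg <- model$config
  n <- length(stream$tokens)
  if (n > cfg$max_pos)
    medsql_error("medsql_config_error",
                 sprintf("stream length %d exceeds max_pos %d", n, cfg$max_pos))
  ids <- vocab_ids(stream$tokens, model$vocab)
  X <- P$Etok[ids, , drop = FALSE] + P$Epos[stream$pos_ids, , drop = FALSE] +
    P$Eseg[stream$seg_ids, , drop = FALSE]
  layers <- vector("list", cfg$enc_layers)
  for (l in seq_len(cfg$enc_layers)) {
    lc <- .cpp_enc_layer_fwd(
      X,
      P[[paste0("l", l, "_Wq")]], P[[paste0("l", l, "_Wk")]],
      P[[paste0("l", l, "_Wv")]], P[[paste0("l", l, "_Wo")]],
      P[[paste0("l", l, "_g1")]], P[[paste0("l", l, "_b1")]],
      P[[paste0("l", l, "_W1")]], P[[paste0("l", l, "_bf1")]],
      P[[paste0("l", l, "_W2")]], P[[paste0("l", l, "_bf2")]],
      P[[paste0("l", l, "_g2")]], P[[paste0("l", l, "_b2")]],
      cfg$enc_heads)
    layers[[l]] <- c(lc, list(X_in = X))
    X <- lc$Y
  }
  pool_groups <- c(lapply(stream$q_spans, `[[`, "pos"), stream$col_pos, stream$tab_pos)
  # group-mean pooling as one aggregated matrix product
  glen <- lengths(pool_groups)
  gidx <- rep(seq_along(pool_groups), glen)
  M <- rowsum(X[unlist(pool_groups), , drop = FALSE], gidx) / glen
  dimnames(M) <- NULL
  pooled <- M %*% t(P$Wpool)
  pooled <- tanh(pooled + matrix(P$bpool, nrow(M), ncol(M), byrow = TRUE))
  m <- length(stream$q_spans); nc <- length(stream$col_pos)
  enc <- structure(list(
    H_X = pooled[seq_len(m), , drop = FALSE],
    H_C = pooled[m + seq_len(nc), , drop = FALSE],
    H_T = pooled[m + nc + seq_len(length(stream$tab_pos)), , drop = FALSE],
    h_cls = X[stream$cls_pos, ],
    width = cfg$enc_dim), class = "medsql_encodings")
  if (keep_cache)
    enc$cache <- list(ids = ids, pos_ids = stream$pos_ids,
                      seg_ids = stream$seg_ids, layers = layers, X_final = X,
                      M = M, pooled = pooled, pool_groups = pool_groups, n = n)
  enc
}

# Backward through pooling and the attention stack. dPooled rows follow the
# pool_groups order; dX_extra adds gradients arriving directly at final
# hidden positions (the CLS vector).
#' @keywords internal
encode_backward <- function(dPooled, dX_extra, enc, model, ge) {
  P <- model$params; cfg <- model$config
  cache <- enc$cache
  dpre <- dPooled * (1 - cache$pooled^2)
  g_add(ge, "Wpool", crossprod(dpre, cache$M))
  g_add(ge, "bpool", colSums(dpre))
  dM <- dpre %*% P$Wpool
  dX <- dX_extra
  glen <- lengths(cache$pool_groups)
  flat <- unlist(cache$pool_groups)
  dRows <- (dM / glen)[rep(seq_along(cache$pool_groups), glen), , drop = FALSE]
  agg <- rowsum(dRows, flat)
  ridx <- as.integer(rownames(agg))
  dX[ridx, ] <- dX[ridx, , drop = FALSE] + agg
  for (l in rev(seq_len(cfg$enc_layers))) {
    lc <- cache$layers[[l]]
    bk <- .cpp_enc_layer_bwd(
      dX, lc, lc$X_in,
      P[[paste0("l", l, "_Wq")]], P[[paste0("l", l, "_Wk")]],
      P[[paste0("l", l, "_Wv")]], P[[paste0("l", l, "_Wo")]],
      P[[paste0("l", l, "_g1")]],
      P[[paste0("l", l, "_W1")]], P[[paste0("l", l, "_W2")]],
      P[[paste0("l", l, "_g2")]],
      cfg$enc_heads)
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2"))
      g_add(ge, paste0("l", l, "_", nm), bk[[paste0("d", nm)]])
    for (nm in c("g1", "b1", "g2", "b2", "bf1", "bf2"))
      g_add(ge, paste0("l", l, "_", nm), as.numeric(bk[[paste0("d", nm)]]))
    dX <- bk$dX
  }
  # embeddings: aggregate by id, then index-add into the accumulators
  add_rows <- function(name, full_rows, groups) {
    if (is.null(ge[[name]])) ge[[name]] <- matrix(0, full_rows, cfg$enc_dim)
    agg <- rowsum(dX, groups)
    ridx <- as.integer(rownames(agg))
    ge[[name]][ridx, ] <- ge[[name]][ridx, , drop = FALSE] + agg
  }
  add_rows("Etok", nrow(P$Etok), cache$ids)
  add_rows("Epos", nrow(P$Epos), cache$pos_ids)
  add_rows("Eseg", nrow(P$Eseg), cache$seg_ids)
  invisible(NULL)
}

#' Initialize the decoder state from the [CLS] representation
#'
#' Hidden state is `tanh(W h_cls + b)`; the cell state starts at zero,
#' the column memory empty.
#'
#' @param h_cls The encoder's CLS vector.
#' @param model A `medsql_model`.
#' @return List with `h`, `c`, `memory`, `step`.
#' @export
init_decoder <- function(h_cls, model) {
  h <- tanh(as.numeric(model$params$Wcls %*% h_cls) + model$params$bcls)
  list(h = h, c = numeric(model$config$dec_dim), memory = integer(), step = 0L)
}
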