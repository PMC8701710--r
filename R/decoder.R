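# Grammar-constrained LSTM decoder. At every step the recurrent input is
# the embedding of the previous action; the hidden state attends over the
# question spans (context v) and over columns+tables (context u); the
# output head depends on the frontier symbol:
#   rule  - softmax over admissible productions of e(r) . Wr [h; v; u]
#   col   - memory-enhanced pointer: sigmoid gate mixes a schema branch
#           (already-selected columns removed) and a memory branch
#   tab   - pointer over the tables containing the selected column
#   val   - start/end span pointers over the question (end >= start)
#
# The backward pass collects one vector pair per step and weight and
# realizes each weight gradient as a single crossprod at the end.

# One LSTM + attention step; M is rbind(H_C, H_T) precomputed per example.
#' @keywords internal
dec_core <- function(P, x_in, h_prev, c_prev, enc, M) {
  D <- ncol(enc$H_X)
  ls <- lstm_forward(x_in, h_prev, c_prev, P$lstm_Wx, P$lstm_Wh, P$lstm_b)
  qx <- as.numeric(P$Wax %*% ls$h)
  sx <- as.numeric(enc$H_X %*% qx) / sqrt(D)
  ax <- nn_softmax(sx)
  v <- as.numeric(crossprod(enc$H_X, ax))
  qm <- as.numeric(P$Wac %*% ls$h)
  sm <- as.numeric(M %*% qm) / sqrt(D)
  am <- nn_softmax(sm)
  u <- as.numeric(crossprod(M, am))
  list(lstm = ls, h = ls$h, c = ls$c, qx = qx, ax = ax, v = v,
       qm = qm, am = am, u = u)
}

# Embedding of the previous action as the recurrent input.
#' @keywords internal
action_input <- function(P, enc, prev) {
  if (is.null(prev)) return(list(x = P$estart, src = list(kind = "start")))
  if (prev$t == "rule") {
    list(x = P$Erule[prev$id, ], src = list(kind = "rule", id = prev$id))
  } else if (prev$t == "col") {
    list(x = enc$H_C[prev$id, ], src = list(kind = "col", id = prev$id))
  } else if (prev$t == "tab") {
    list(x = enc$H_T[prev$id, ], src = list(kind = "tab", id = prev$id))
  } else {
    rows <- prev$span_s:prev$span_e
    list(x = colMeans(enc$H_X[rows, , drop = FALSE]),
         src = list(kind = "val", rows = rows))
  }
}

# Head forwards -------------------------------------------------------------

#' @keywords internal
head_rule <- function(P, core, mask) {
  feat <- c(core$h, core$v, core$u)
  logits <- as.numeric(P$Wr %*% feat) + P$br
  list(p = nn_softmax_masked(logits, mask), feat = feat, mask = mask)
}

#' @keywords internal
head_col <- function(P, core, enc, sch_mask, mem_mask) {
  D <- ncol(enc$H_C)
  hv <- c(core$h, core$v)
  qs <- as.numeric(P$Wsch %*% hv)
  ss <- as.numeric(enc$H_C %*% qs) / sqrt(D)
  p_s <- nn_softmax_masked(ss, sch_mask)
  mem_empty <- !any(mem_mask)
  if (mem_empty) {
    g <- 1
    p_m <- numeric(nrow(enc$H_C))
    qm <- NULL
    p <- p_s
  } else {
    qm <- as.numeric(P$Wmem %*% hv)
    sm <- as.numeric(enc$H_C %*% qm) / sqrt(D)
    p_m <- nn_softmax_masked(sm, mem_mask)
    g <- nn_sigmoid(sum(P$wg * hv) + P$bg)
    p <- g * p_s + (1 - g) * p_m
  }
  list(p = p, p_s = p_s, p_m = p_m, g = g, hv = hv, qs = qs, qm = qm,
       sch_mask = sch_mask, mem_mask = mem_mask, mem_empty = mem_empty)
}

#' @keywords internal
head_tab <- function(P, core, enc, mask) {
  D <- ncol(enc$H_T)
  hv <- c(core$h, core$v)
  qt <- as.numeric(P$Wtab %*% hv)
  st <- as.numeric(enc$H_T %*% qt) / sqrt(D)
  list(p = nn_softmax_masked(st, mask), hv = hv, qt = qt, mask = mask)
}

#' @keywords internal
head_val_start <- function(P, core, enc) {
  D <- ncol(enc$H_X)
  hv <- c(core$h, core$v)
  qvs <- as.numeric(P$Wvs %*% hv)
  ss <- as.numeric(enc$H_X %*% qvs) / sqrt(D)
  list(p = nn_softmax(ss), hv = hv, qvs = qvs)
}

#' @keywords internal
head_val_end <- function(P, core, enc, s_span) {
  D <- ncol(enc$H_X)
  he <- c(core$h, core$v, enc$H_X[s_span, ])
  qve <- as.numeric(P$Wve %*% he)
  se <- as.numeric(enc$H_X %*% qve) / sqrt(D)
  mask <- seq_len(nrow(enc$H_X)) >= s_span
  list(p = nn_softmax_masked(se, mask), he = he, qve = qve, mask = mask,
       s_span = s_span)
}

# Pair collector: per-weight lists of (gradient row, input row), realized
# as one crossprod per weight after the step loop.
#' @keywords internal
pc_new <- function() new.env(parent = emptyenv())

#' @keywords internal
pc_push <- function(pc, name, d, x) {
  e <- pc[[name]]
  if (is.null(e)) {
    e <- list(d = list(), x = list())
  }
  e$d[[length(e$d) + 1L]] <- d
  e$x[[length(e$x) + 1L]] <- x
  pc[[name]] <- e
  invisible(NULL)
}

#' @keywords internal
pc_flush <- function(pc, ge, bias_map = list()) {
  for (name in ls(pc)) {
    e <- pc[[name]]
    Dm <- do.call(rbind, e$d)
    Xm <- do.call(rbind, e$x)
    g_add(ge, name, crossprod(Dm, Xm))
    bn <- bias_map[[name]]
    if (!is.null(bn)) g_add(ge, bn, colSums(Dm))
  }
  invisible(NULL)
}

# Teacher-forced pass --------------------------------------------------------

# `prep` comes from prepare_example(): per-step frontier kind, masks, gold
# indices, and the previous gold action. Returns the loss; when `ge` is a
# gradient environment the backward pass runs too; when want_dists, the
# per-step action distributions (token-indexed for value steps).
#' @keywords internal
teacher_pass <- function(model, prep, enc, ge = NULL, want_dists = FALSE) {
  P <- model$params
  D <- model$config$enc_dim
  Hd <- model$config$dec_dim
  M <- rbind(enc$H_C, enc$H_T)
  st0 <- init_decoder(enc$h_cls, model)
  h <- st0$h; c0 <- st0$c
  n_steps <- length(prep$steps)
  caches <- if (!is.null(ge)) vector("list", n_steps)
  dists <- if (want_dists) vector("list", n_steps)
  loss <- 0
  for (i in seq_len(n_steps)) {
    stp <- prep$steps[[i]]
    ai <- action_input(P, enc, stp$prev)
    core <- dec_core(P, ai$x, h, c0, enc, M)
    if (stp$kind == "rule") {
      hd <- head_rule(P, core, stp$mask)
      pg <- hd$p[stp$gold]
      if (want_dists) dists[[i]] <- list(kind = "rule", p = hd$p)
    } else if (stp$kind == "col") {
      hd <- head_col(P, core, enc, stp$sch_mask, stp$mem_mask)
      pg <- hd$p[stp$gold]
      if (want_dists) dists[[i]] <- list(kind = "col", p = hd$p)
    } else if (stp$kind == "tab") {
      hd <- head_tab(P, core, enc, stp$mask)
      pg <- hd$p[stp$gold]
      if (want_dists) dists[[i]] <- list(kind = "tab", p = hd$p)
    } else {
      hs <- head_val_start(P, core, enc)
      he <- head_val_end(P, core, enc, stp$gold_s)
      pg <- hs$p[stp$gold_s] * he$p[stp$gold_e]
      hd <- list(start = hs, end = he)
      if (want_dists)
        dists[[i]] <- list(kind = "val",
                           p_start = span_to_token_dist(hs$p, prep$stream, "first"),
                           p_end = span_to_token_dist(he$p, prep$stream, "last"))
    }
    if (pg <= 0 || !is.finite(pg))
      medsql_error("medsql_data_error",
                   sprintf("gold action at step %d has zero probability mass", i))
    loss <- loss - log(pg)
    if (!is.null(ge)) caches[[i]] <- list(core = core, head = hd, x_src = ai$src,
                                          x_in = ai$x, h_prev = h, c_prev = c0)
    h <- core$h; c0 <- core$c
  }

  if (!is.null(ge)) {
    nc <- nrow(enc$H_C)
    acc <- new.env(parent = emptyenv())
    acc$H_X <- matrix(0, nrow(enc$H_X), D)
    acc$H_C <- matrix(0, nc, D)
    acc$H_T <- matrix(0, nrow(enc$H_T), D)
    acc$dErule <- matrix(0, nrow(P$Erule), D)
    pc <- pc_new()
    sqD <- sqrt(D)
    dh <- numeric(Hd)
    dc <- numeric(Hd)
    for (i in rev(seq_len(n_steps))) {
      cc <- caches[[i]]
      stp <- prep$steps[[i]]
      core <- cc$core
      dv <- numeric(D); du <- numeric(D)
      if (stp$kind == "rule") {
        hd <- cc$head
        dlog <- hd$p
        dlog[stp$gold] <- dlog[stp$gold] - 1
        pc_push(pc, "Wr", dlog, hd$feat)
        dfeat <- as.numeric(crossprod(P$Wr, dlog))
        dh <- dh + dfeat[seq_len(Hd)]
        dv <- dv + dfeat[Hd + seq_len(D)]
        du <- du + dfeat[Hd + D + seq_len(D)]
      } else if (stp$kind == "col") {
        hd <- cc$head
        dhv <- numeric(length(hd$hv))
        in_mem <- stp$mem_mask[stp$gold]
        if (!in_mem) {
          ds <- hd$p_s
          ds[stp$gold] <- ds[stp$gold] - 1
          dqs <- as.numeric(crossprod(enc$H_C, ds)) / sqD
          acc$H_C <- acc$H_C + outer(ds / sqD, hd$qs)
          pc_push(pc, "Wsch", dqs, hd$hv)
          dhv <- dhv + as.numeric(crossprod(P$Wsch, dqs))
          if (!hd$mem_empty) {
            dpg <- -(1 - hd$g)
            g_add(ge, "wg", dpg * hd$hv)
            g_add(ge, "bg", dpg)
            dhv <- dhv + dpg * P$wg
          }
        } else {
          ds <- hd$p_m
          ds[stp$gold] <- ds[stp$gold] - 1
          dqm <- as.numeric(crossprod(enc$H_C, ds)) / sqD
          acc$H_C <- acc$H_C + outer(ds / sqD, hd$qm)
          pc_push(pc, "Wmem", dqm, hd$hv)
          dhv <- dhv + as.numeric(crossprod(P$Wmem, dqm))
          dpg <- hd$g
          g_add(ge, "wg", dpg * hd$hv)
          g_add(ge, "bg", dpg)
          dhv <- dhv + dpg * P$wg
        }
        dh <- dh + dhv[seq_len(Hd)]
        dv <- dv + dhv[Hd + seq_len(D)]
      } else if (stp$kind == "tab") {
        hd <- cc$head
        ds <- hd$p
        ds[stp$gold] <- ds[stp$gold] - 1
        dqt <- as.numeric(crossprod(enc$H_T, ds)) / sqD
        acc$H_T <- acc$H_T + outer(ds / sqD, hd$qt)
        pc_push(pc, "Wtab", dqt, hd$hv)
        dhv <- as.numeric(crossprod(P$Wtab, dqt))
        dh <- dh + dhv[seq_len(Hd)]
        dv <- dv + dhv[Hd + seq_len(D)]
      } else {
        hs <- cc$head$start; hev <- cc$head$end
        # end pointer
        ds <- hev$p
        ds[stp$gold_e] <- ds[stp$gold_e] - 1
        dqve <- as.numeric(crossprod(enc$H_X, ds)) / sqD
        acc$H_X <- acc$H_X + outer(ds / sqD, hev$qve)
        pc_push(pc, "Wve", dqve, hev$he)
        dhe <- as.numeric(crossprod(P$Wve, dqve))
        dh <- dh + dhe[seq_len(Hd)]
        dv <- dv + dhe[Hd + seq_len(D)]
        acc$H_X[stp$gold_s, ] <- acc$H_X[stp$gold_s, ] + dhe[Hd + D + seq_len(D)]
        # start pointer
        ds <- hs$p
        ds[stp$gold_s] <- ds[stp$gold_s] - 1
        dqvs <- as.numeric(crossprod(enc$H_X, ds)) / sqD
        acc$H_X <- acc$H_X + outer(ds / sqD, hs$qvs)
        pc_push(pc, "Wvs", dqvs, hs$hv)
        dhv <- as.numeric(crossprod(P$Wvs, dqvs))
        dh <- dh + dhv[seq_len(Hd)]
        dv <- dv + dhv[Hd + seq_len(D)]
      }
      # attention contexts
      if (any(du != 0)) {
        da <- as.numeric(M %*% du)
        ds <- core$am * (da - sum(da * core$am))
        dqm <- as.numeric(crossprod(M, ds)) / sqD
        dM <- outer(ds / sqD, core$qm) + outer(core$am, du)
        acc$H_C <- acc$H_C + dM[seq_len(nc), , drop = FALSE]
        acc$H_T <- acc$H_T + dM[nc + seq_len(nrow(enc$H_T)), , drop = FALSE]
        pc_push(pc, "Wac", dqm, core$h)
        dh <- dh + as.numeric(crossprod(P$Wac, dqm))
      }
      if (any(dv != 0)) {
        da <- as.numeric(enc$H_X %*% dv)
        ds <- core$ax * (da - sum(da * core$ax))
        dqx <- as.numeric(crossprod(enc$H_X, ds)) / sqD
        acc$H_X <- acc$H_X + outer(ds / sqD, core$qx) + outer(core$ax, dv)
        pc_push(pc, "Wax", dqx, core$h)
        dh <- dh + as.numeric(crossprod(P$Wax, dqx))
      }
      lb <- lstm_backward(dh, dc, core$lstm, cc$x_in, cc$h_prev, cc$c_prev,
                          P$lstm_Wx, P$lstm_Wh)
      pc_push(pc, "lstm_Wx", lb$dz, cc$x_in)
      pc_push(pc, "lstm_Wh", lb$dz, cc$h_prev)
      route_dx(lb$dx, cc$x_src, acc, ge)
      dh <- lb$dh_prev
      dc <- lb$dc_prev
    }
    pc_flush(pc, ge, bias_map = list(Wr = "br", lstm_Wx = "lstm_b"))
    g_add(ge, "Erule", acc$dErule)
    # decoder init
    h0 <- st0$h
    dpre <- dh * (1 - h0^2)
    g_add(ge, "Wcls", outer(dpre, enc$h_cls))
    g_add(ge, "bcls", dpre)
    dh_cls <- as.numeric(crossprod(P$Wcls, dpre))
    # through pooling + encoder
    dPooled <- rbind(acc$H_X, acc$H_C, acc$H_T)
    dX_extra <- matrix(0, enc$cache$n, D)
    dX_extra[prep$stream$cls_pos, ] <- dh_cls
    encode_backward(dPooled, dX_extra, enc, model, ge)
  }
  list(loss = loss, dists = dists)
}

#' @keywords internal
route_dx <- function(dx, src, acc, ge) {
  if (src$kind == "start") g_add(ge, "estart", dx)
  else if (src$kind == "rule") acc$dErule[src$id, ] <- acc$dErule[src$id, ] + dx
  else if (src$kind == "col") acc$H_C[src$id, ] <- acc$H_C[src$id, ] + dx
  else if (src$kind == "tab") acc$H_T[src$id, ] <- acc$H_T[src$id, ] + dx
  else {
    k <- length(src$rows)
    acc$H_X[src$rows, ] <- acc$H_X[src$rows, , drop = FALSE] +
      matrix(dx / k, k, length(dx), byrow = TRUE)
  }
  invisible(NULL)
}

# Map a span-level pointer distribution to question-token level: a span's
# mass sits on its first (start pointer) or last (end pointer) token.
#' @keywords internal
span_to_token_dist <- function(p_span, stream, which = c("first", "last")) {
  which <- match.arg(which)
  n_tok <- max(vapply(stream$q_spans, `[[`, integer(1), "to"))
  p <- numeric(n_tok)
  for (k in seq_along(stream$q_spans)) {
    sp <- stream$q_spans[[k]]
    tok <- if (which == "first") sp$from else sp$to
    p[tok] <- p[tok] + p_span[k]
  }
  p
}
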