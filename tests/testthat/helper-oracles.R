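# Independent oracles, written deliberately as plain scalar loops so they
# share no code path with the package implementations they check.

# Hand-unrolled forward pass of the variable-wise LSTM with mixed attention
# for a single window (T x V matrix). Follows the recurrence definition
# step by step with scalar indexing.
oracle_imv_forward <- function(params, window) {
  V <- attr(params, "V"); d <- attr(params, "d")
  Tt <- nrow(window)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- matrix(0, V, d)      # variable-wise hidden blocks
  cvec <- rep(0, V * d)
  Hs <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    # candidate update per variable
    j <- matrix(0, V, d)
    for (v in 1:V) for (a in 1:d) {
      acc <- params$b[v, a] + params$U[v, a] * window[t, v]
      for (bb in 1:d) acc <- acc + params$W[a, bb, v] * h[v, bb]
      j[v, a] <- tanh(acc)
    }
    # variable-wise gates over [h_v; x_v]
    iv <- matrix(0, V, d); fv <- matrix(0, V, d); ov <- matrix(0, V, d)
    for (v in 1:V) {
      zin <- c(h[v, ], window[t, v])
      for (a in 1:d) {
        gi <- params$bg[v, a]
        gf <- params$bg[v, d + a]
        go <- params$bg[v, 2 * d + a]
        for (q in seq_along(zin)) {
          gi <- gi + zin[q] * params$Wg[q, a, v]
          gf <- gf + zin[q] * params$Wg[q, d + a, v]
          go <- go + zin[q] * params$Wg[q, 2 * d + a, v]
        }
        iv[v, a] <- sig(gi); fv[v, a] <- sig(gf); ov[v, a] <- sig(go)
      }
    }
    ivec <- as.vector(t(iv)); fvec <- as.vector(t(fv)); ovec <- as.vector(t(ov))
    jflat <- as.vector(t(j))
    cvec <- fvec * cvec + ivec * jflat
    hflat_new <- ovec * tanh(cvec)
    h <- matrix(hflat_new, V, d, byrow = TRUE)
    Hs[[t]] <- h
  }
  # temporal attention per variable
  escore <- matrix(0, V, Tt)
  for (v in 1:V) for (t in 1:Tt) {
    s <- numeric(d)
    for (a in 1:d) {
      acc <- params$balpha[v, a]
      for (bb in 1:d) acc <- acc + params$Aalpha[a, bb, v] * Hs[[t]][v, bb]
      s[a] <- tanh(acc)
    }
    escore[v, t] <- sum(s * params$ualpha[v, ])
  }
  alpha <- matrix(0, V, Tt)
  for (v in 1:V) alpha[v, ] <- exp(escore[v, ] - max(escore[v, ])) /
    sum(exp(escore[v, ] - max(escore[v, ])))
  # contexts, variable attention, heads
  eb <- numeric(V); m <- numeric(V)
  zs <- vector("list", V)
  for (v in 1:V) {
    gv <- numeric(d)
    for (t in 1:Tt) gv <- gv + alpha[v, t] * Hs[[t]][v, ]
    zv <- c(gv, Hs[[Tt]][v, ])
    zs[[v]] <- zv
    q <- numeric(d)
    for (a in 1:d) {
      acc <- params$bbeta[a]
      for (bb in 1:(2 * d)) acc <- acc + params$Wbeta[a, bb] * zv[bb]
      q[a] <- tanh(acc)
    }
    eb[v] <- sum(q * params$ubeta)
    m[v] <- sum(params$Whead[v, ] * zv) + params$bhead[v]
  }
  beta <- exp(eb - max(eb)) / sum(exp(eb - max(eb)))
  logit <- sum(beta * m)
  list(probability = sig(logit), alpha = alpha, beta = beta)
}

# Brute-force greedy 1:k matcher: explicit O(cases x controls) rescan with
# the stated semantics (descending case score, min |delta|, ties to the
# smaller person id, without replacement).
oracle_greedy_match <- function(scores, labels, k) {
  ids <- names(scores)
  cases <- ids[labels[ids] == 1]
  cases <- cases[order(-scores[cases], cases)]
  avail <- ids[labels[ids] == 0]
  pairs <- NULL
  for (cid in cases) {
    for (r in seq_len(k)) {
      if (!length(avail)) break
      dd <- abs(scores[avail] - scores[[cid]])
      best <- avail[dd == min(dd)]
      pick <- sort(best)[1]
      pairs <- rbind(pairs, data.frame(case_id = cid, control_id = pick,
                                       rank = r, stringsAsFactors = FALSE))
      avail <- setdiff(avail, pick)
    }
  }
  pairs
}

# Pairwise-enumeration AUROC (ties count one half).
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Beta-weighted attention aggregation recomputed with explicit loops.
oracle_aggregate <- function(alphas, betas) {
  N <- dim(alphas)[1]; V <- dim(alphas)[2]; Tt <- dim(alphas)[3]
  S <- matrix(0, V, Tt)
  for (v in 1:V) for (t in 1:Tt) {
    num <- 0; den <- 0
    for (s in 1:N) {
      num <- num + betas[s, v] * alphas[s, v, t]
      den <- den + betas[s, v]
    }
    S[v, t] <- num / den
  }
  S
}
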