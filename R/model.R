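# Interpretable multivariable LSTM (variable-wise/tensorized gates).
#
# Each input variable v keeps its own d-dimensional hidden-state block whose
# candidate update and input/forget/output gates see only that variable's
# input and previous block, so a block can never encode another variable's
# history and the attention attribution stays faithful. A per-variable
# temporal attention (alpha, over time steps) and a shared variable
# attention (beta, over variables) are mixed into the prediction, exposing
# both when-it-mattered and what-mattered importances.
#
# The forward pass, reverse-mode gradients, Adam optimiser and early
# stopping are implemented here directly on base R matrices; the whole
# network state is a flat list of numeric arrays, which keeps analytic
# gradients checkable against finite differences parameter-by-parameter.

#' Hyperparameters for the IMV-LSTM
#'
#' Defaults follow the training protocol used throughout the pipeline:
#' Adam, learning rate 1e-3, batch size 64, up to 200 epochs with early
#' stopping after 20 epochs without validation-loss improvement.
#'
#' @param d Hidden units per variable.
#' @param epochs Maximum training epochs.
#' @param batch Mini-batch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience in epochs.
#' @param seed Seed for initialization and batch shuffling.
#' @param threshold Decision threshold for class metrics.
#' @param pos_weight Weight positive windows by `n_neg / n_pos` in the loss
#'   (class-imbalance correction); set `FALSE` for the unweighted loss.
#' @return An `imv_hyperparams` list.
#' @export
imv_hyperparams <- function(d = 4L, epochs = 200L, batch = 64L, lr = 1e-3,
                            patience = 20L, seed = 1L, threshold = 0.5,
                            pos_weight = TRUE) {
  if (d < 1L) stop_config("d must be >= 1")
  if (lr <= 0) stop_config("lr must be positive")
  structure(list(d = as.integer(d), epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr,
                 patience = as.integer(patience), seed = as.integer(seed),
                 threshold = threshold, pos_weight = isTRUE(pos_weight)),
            class = "imv_hyperparams")
}

# Parameter container: flat named list of numeric arrays.
#   U     V x d          per-variable input weights (scalar input per variable)
#   W     d x d x V      per-variable recurrent weights (candidate update)
#   b     V x d          candidate biases
#   Wg    (d+1) x 3d x V per-variable input/forget/output gates over [h_v; x_v]
#   bg    V x 3d         gate biases (forget initialised to 1)
#   Aalpha d x d x V, balpha V x d, ualpha V x d   temporal-attention scorer
#   Wbeta  d x 2d,  bbeta d,  ubeta d              variable-attention scorer
#   Whead  V x 2d,  bhead V                        per-variable output heads
imv_init <- function(V, d, seed = 1L) {
  set.seed(seed)
  rn <- function(...) array(stats::rnorm(prod(c(...)), 0, 0.2), dim = c(...))
  bg <- matrix(rep(c(rep(0, d), rep(1, d), rep(0, d)), each = V), V, 3 * d)
  params <- list(
    U = rn(V, d), W = rn(d, d, V), b = array(0, c(V, d)),
    Wg = rn(d + 1, 3 * d, V), bg = bg,
    Aalpha = rn(d, d, V), balpha = array(0, c(V, d)), ualpha = rn(V, d),
    Wbeta = rn(d, 2 * d), bbeta = rep(0, d), ubeta = rn(d),
    Whead = rn(V, 2 * d), bhead = rep(0, V))
  attr(params, "V") <- V
  attr(params, "d") <- d
  params
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Core forward pass over a batch. x: N x T x V array. Returns probabilities
# and attention; with cache = TRUE also every intermediate needed by
# imv_backward.
imv_forward_batch <- function(params, x, cache = FALSE) {
  V <- attr(params, "V"); d <- attr(params, "d"); Vd <- V * d
  stopifnot(length(dim(x)) == 3L)
  N <- dim(x)[1]; Tt <- dim(x)[2]
  if (dim(x)[3] != V) stop_contract("window has ", dim(x)[3],
                                    " variables; model expects ", V)
  blk <- function(v) ((v - 1L) * d + 1L):(v * d)
  h <- matrix(0, N, Vd); cc <- matrix(0, N, Vd)
  H <- vector("list", Tt)
  CC <- if (cache) vector("list", Tt) else NULL
  TC <- if (cache) vector("list", Tt) else NULL
  J <- if (cache) vector("list", Tt) else NULL
  G <- if (cache) vector("list", Tt) else NULL   # gates i, f, o (N x 3Vd)
  Hprev <- if (cache) vector("list", Tt) else NULL
  for (t in seq_len(Tt)) {
    xt <- matrix(x[, t, ], N, V)
    j <- matrix(0, N, Vd)
    gi <- matrix(0, N, Vd); gf <- matrix(0, N, Vd); go <- matrix(0, N, Vd)
    for (v in seq_len(V)) {
      hv <- h[, blk(v), drop = FALSE]
      j[, blk(v)] <- tanh(hv %*% t(params$W[, , v]) +
                            outer(xt[, v], params$U[v, ]) +
                            matrix(params$b[v, ], N, d, byrow = TRUE))
      a <- cbind(hv, xt[, v]) %*% params$Wg[, , v] +
        matrix(params$bg[v, ], N, 3 * d, byrow = TRUE)
      gi[, blk(v)] <- .sigmoid(a[, 1:d, drop = FALSE])
      gf[, blk(v)] <- .sigmoid(a[, d + 1:d, drop = FALSE])
      go[, blk(v)] <- .sigmoid(a[, 2 * d + 1:d, drop = FALSE])
    }
    if (cache) Hprev[[t]] <- h
    cc_new <- gf * cc + gi * j
    tc <- tanh(cc_new)
    hn <- go * tc
    if (cache) {
      J[[t]] <- j; G[[t]] <- cbind(gi, gf, go); CC[[t]] <- cc; TC[[t]] <- tc
    }
    cc <- cc_new; h <- hn
    H[[t]] <- h
  }
  # temporal attention
  e <- array(0, c(N, V, Tt))
  S <- if (cache) vector("list", Tt) else NULL
  for (t in seq_len(Tt)) {
    st <- matrix(0, N, Vd)
    for (v in seq_len(V)) {
      s_tv <- tanh(H[[t]][, blk(v), drop = FALSE] %*% t(params$Aalpha[, , v]) +
                     matrix(params$balpha[v, ], N, d, byrow = TRUE))
      st[, blk(v)] <- s_tv
      e[, v, t] <- s_tv %*% params$ualpha[v, ]
    }
    if (cache) S[[t]] <- st
  }
  emax <- apply(e, c(1, 2), max)
  alpha <- exp(e - array(emax, c(N, V, Tt)))
  asum <- apply(alpha, c(1, 2), sum)
  alpha <- alpha / array(asum, c(N, V, Tt))
  # contexts and variable attention
  gctx <- matrix(0, N, Vd)
  for (t in seq_len(Tt)) {
    for (v in seq_len(V)) {
      gctx[, blk(v)] <- gctx[, blk(v)] + alpha[, v, t] * H[[t]][, blk(v), drop = FALSE]
    }
  }
  hT <- H[[Tt]]
  eb <- matrix(0, N, V)
  m <- matrix(0, N, V)
  Q <- if (cache) vector("list", V) else NULL
  for (v in seq_len(V)) {
    zv <- cbind(gctx[, blk(v), drop = FALSE], hT[, blk(v), drop = FALSE])
    qv <- tanh(zv %*% t(params$Wbeta) + matrix(params$bbeta, N, d, byrow = TRUE))
    eb[, v] <- qv %*% params$ubeta
    m[, v] <- zv %*% params$Whead[v, ] + params$bhead[v]
    if (cache) Q[[v]] <- qv
  }
  ebmax <- apply(eb, 1, max)
  beta <- exp(eb - ebmax)
  beta <- beta / rowSums(beta)
  logit <- rowSums(beta * m)
  prob <- .sigmoid(logit)
  out <- list(prob = prob, alpha = alpha, beta = beta, logit = logit)
  if (cache) {
    out$cache <- list(H = H, CC = CC, TC = TC, J = J, G = G,
                      Hprev = Hprev, S = S, Q = Q, gctx = gctx, m = m,
                      x = x, N = N, Tt = Tt)
  }
  out
}

# Reverse-mode gradients of the mean weighted binary cross-entropy.
# Returns a gradient list with the same shapes as `params` plus the loss.
imv_backward <- function(params, fwd, y, weight = rep(1, length(y))) {
  V <- attr(params, "V"); d <- attr(params, "d"); Vd <- V * d
  ca <- fwd$cache
  N <- ca$N; Tt <- ca$Tt
  blk <- function(v) ((v - 1L) * d + 1L):(v * d)
  p <- fwd$prob
  eps <- 1e-12
  loss <- -mean(weight * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
  dlogit <- weight * (p - y) / N

  g <- list(U = array(0, dim(params$U)), W = array(0, dim(params$W)),
            b = array(0, dim(params$b)), Wg = array(0, dim(params$Wg)),
            bg = array(0, dim(params$bg)),
            Aalpha = array(0, dim(params$Aalpha)),
            balpha = array(0, dim(params$balpha)),
            ualpha = array(0, dim(params$ualpha)),
            Wbeta = array(0, dim(params$Wbeta)),
            bbeta = numeric(length(params$bbeta)),
            ubeta = numeric(length(params$ubeta)),
            Whead = array(0, dim(params$Whead)),
            bhead = numeric(length(params$bhead)))

  beta <- fwd$beta; m <- ca$m
  dm <- beta * dlogit                      # N x V
  dbeta <- m * dlogit
  deb <- beta * (dbeta - rowSums(beta * dbeta))   # softmax over v
  hT <- ca$H[[Tt]]
  dgctx <- matrix(0, N, Vd)
  dhT_extra <- matrix(0, N, Vd)
  for (v in seq_len(V)) {
    zv <- cbind(ca$gctx[, blk(v), drop = FALSE], hT[, blk(v), drop = FALSE])
    qv <- ca$Q[[v]]
    # variable-attention scorer
    g$ubeta <- g$ubeta + drop(crossprod(qv, deb[, v]))
    dpre_q <- (deb[, v] %o% params$ubeta) * (1 - qv^2)
    g$Wbeta <- g$Wbeta + crossprod(dpre_q, zv)
    g$bbeta <- g$bbeta + colSums(dpre_q)
    dzv <- dpre_q %*% params$Wbeta
    # output head
    g$Whead[v, ] <- g$Whead[v, ] + drop(crossprod(zv, dm[, v]))
    g$bhead[v] <- g$bhead[v] + sum(dm[, v])
    dzv <- dzv + dm[, v] %o% params$Whead[v, ]
    dgctx[, blk(v)] <- dzv[, 1:d, drop = FALSE]
    dhT_extra[, blk(v)] <- dzv[, d + 1:d, drop = FALSE]
  }

  # context -> alpha and hidden states
  alpha <- fwd$alpha
  dalpha <- array(0, c(N, V, Tt))
  dh_att <- lapply(seq_len(Tt), function(t) matrix(0, N, Vd))
  for (t in seq_len(Tt)) {
    Ht <- ca$H[[t]]
    for (v in seq_len(V)) {
      dalpha[, v, t] <- rowSums(dgctx[, blk(v), drop = FALSE] *
                                  Ht[, blk(v), drop = FALSE])
      dh_att[[t]][, blk(v)] <- dh_att[[t]][, blk(v)] +
        alpha[, v, t] * dgctx[, blk(v), drop = FALSE]
    }
  }
  # softmax over t, then the temporal scorer
  aw <- apply(alpha * dalpha, c(1, 2), sum)        # N x V
  de <- alpha * (dalpha - array(aw, c(N, V, Tt)))
  for (t in seq_len(Tt)) {
    Ht <- ca$H[[t]]
    St <- ca$S[[t]]
    for (v in seq_len(V)) {
      s_tv <- St[, blk(v), drop = FALSE]
      de_vt <- de[, v, t]
      g$ualpha[v, ] <- g$ualpha[v, ] + drop(crossprod(s_tv, de_vt))
      dpre_s <- (de_vt %o% params$ualpha[v, ]) * (1 - s_tv^2)
      g$Aalpha[, , v] <- g$Aalpha[, , v] +
        crossprod(dpre_s, Ht[, blk(v), drop = FALSE])
      g$balpha[v, ] <- g$balpha[v, ] + colSums(dpre_s)
      dh_att[[t]][, blk(v)] <- dh_att[[t]][, blk(v)] + dpre_s %*% params$Aalpha[, , v]
    }
  }
  dh_att[[Tt]] <- dh_att[[Tt]] + dhT_extra

  # backprop through time
  dh_rec <- matrix(0, N, Vd)
  dc_next <- matrix(0, N, Vd)
  for (t in rev(seq_len(Tt))) {
    dh <- dh_att[[t]] + dh_rec
    gi <- ca$G[[t]][, 1:Vd, drop = FALSE]
    gf <- ca$G[[t]][, Vd + 1:Vd, drop = FALSE]
    go <- ca$G[[t]][, 2 * Vd + 1:Vd, drop = FALSE]
    tc <- ca$TC[[t]]
    do_ <- dh * tc
    dc <- dc_next + dh * go * (1 - tc^2)
    df <- dc * ca$CC[[t]]       # CC holds c_{t-1}
    di <- dc * ca$J[[t]]
    dj <- dc * gi
    dc_next <- dc * gf
    dai <- di * gi * (1 - gi)
    daf <- df * gf * (1 - gf)
    dao <- do_ * go * (1 - go)
    dh_prev <- matrix(0, N, Vd)
    hprev <- ca$Hprev[[t]]
    xt <- matrix(ca$x[, t, ], N, V)
    for (v in seq_len(V)) {
      bv <- blk(v)
      dAv <- cbind(dai[, bv, drop = FALSE], daf[, bv, drop = FALSE],
                   dao[, bv, drop = FALSE])                 # N x 3d
      zin <- cbind(hprev[, bv, drop = FALSE], xt[, v])
      g$Wg[, , v] <- g$Wg[, , v] + crossprod(zin, dAv)
      g$bg[v, ] <- g$bg[v, ] + colSums(dAv)
      dzv <- tcrossprod(dAv, params$Wg[, , v])              # N x (d+1)
      dh_prev[, bv] <- dzv[, 1:d, drop = FALSE]
      jv <- ca$J[[t]][, bv, drop = FALSE]
      dpre_j <- dj[, bv, drop = FALSE] * (1 - jv^2)
      g$W[, , v] <- g$W[, , v] + crossprod(dpre_j, hprev[, bv, drop = FALSE])
      g$U[v, ] <- g$U[v, ] + colSums(dpre_j * xt[, v])
      g$b[v, ] <- g$b[v, ] + colSums(dpre_j)
      dh_prev[, bv] <- dh_prev[, bv] + dpre_j %*% params$W[, , v]
    }
    dh_rec <- dh_prev
  }
  list(grad = g, loss = loss)
}

#' Forward pass of the IMV-LSTM on a single window
#'
#' @param params A parameter list from `imv_init()` or a trained model's
#'   `$params`.
#' @param window Numeric T x V matrix (standardized, fully imputed).
#' @return List: `probability` (scalar in (0,1)), `alpha` (V x T temporal
#'   attention, each row summing to 1), `beta` (variable attention summing
#'   to 1).
#' @export
imv_forward <- function(params, window) {
  window <- as.matrix(window)
  x <- array(window, c(1, nrow(window), ncol(window)))
  fwd <- imv_forward_batch(params, x)
  list(probability = fwd$prob[1],
       alpha = matrix(fwd$alpha[1, , ], dim(fwd$alpha)[2], dim(fwd$alpha)[3]),
       beta = drop(fwd$beta[1, ]))
}

# flatten/unflatten for finite-difference gradient checks
params_to_vector <- function(params) {
  unlist(lapply(params, as.vector), use.names = FALSE)
}

vector_to_params <- function(theta, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    val <- theta[pos + seq_len(n)]
    if (!is.null(dim(template[[nm]]))) dim(val) <- dim(template[[nm]])
    out[[nm]] <- val
    pos <- pos + n
  }
  attributes(out) <- attributes(template)
  out
}

# Loss and analytic gradient as a function of the flat parameter vector;
# used by the optimiser and by gradient-correctness checks.
imv_loss_grad <- function(params, x, y, weight = rep(1, length(y))) {
  fwd <- imv_forward_batch(params, x, cache = TRUE)
  bwd <- imv_backward(params, fwd, y, weight)
  list(loss = bwd$loss, grad = bwd$grad)
}

imv_loss <- function(params, x, y, weight = rep(1, length(y))) {
  p <- imv_forward_batch(params, x)$prob
  eps <- 1e-12
  -mean(weight * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

#' Train the IMV-LSTM
#'
#' Minimises the (optionally class-weighted) binary cross-entropy with Adam
#' over seeded shuffled mini-batches, early-stopping on validation loss:
#' training halts when the validation loss has not improved for
#' `hyper$patience` consecutive epochs, and the parameters of the best
#' validation epoch are returned.
#'
#' @param train,validation `window_tensor`s (standardized).
#' @param hyper An [imv_hyperparams()].
#' @param verbose Print per-epoch losses.
#' @return An `imv_model`: `params`, `hyper`, `variables`, `history`
#'   (per-epoch train/validation loss), `best_epoch`.
#' @export
imv_train <- function(train, validation, hyper = imv_hyperparams(),
                      verbose = FALSE) {
  x <- train$data; y <- train$labels
  xv <- validation$data; yv <- validation$labels
  if (length(unique(y)) < 2L) stop_contract("training set must contain both classes")
  V <- dim(x)[3]
  set.seed(hyper$seed)
  params <- imv_init(V, hyper$d, seed = hyper$seed)
  w_pos <- if (hyper$pos_weight) sum(y == 0) / sum(y == 1) else 1
  weight <- ifelse(y == 1, w_pos, 1)
  wv <- ifelse(yv == 1, w_pos, 1)

  # Adam state mirrors the parameter structure
  mom <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  vel <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(y)
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = hyper$batch)) {
      sel <- ord[start:min(start + hyper$batch - 1L, n)]
      lg <- imv_loss_grad(params, x[sel, , , drop = FALSE], y[sel], weight[sel])
      step <- step + 1L
      for (nm in names(params)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * lg$grad[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * lg$grad[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - hyper$lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    vl <- imv_loss(params, xv, yv, wv)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = vl))
    if (verbose) message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                                 ep_loss / nb, vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= hyper$patience) break
    }
  }
  structure(list(params = best$params, hyper = hyper,
                 variables = dimnames(x)[[3]], history = hist,
                 best_epoch = best$epoch, pos_weight = w_pos),
            class = "imv_model")
}

#' Predict probabilities and attention for a set of windows
#'
#' Vectorized, order-preserving forward pass.
#'
#' @param object An `imv_model`.
#' @param windows A `window_tensor` or a windows x T x V array.
#' @param chunk Internal batch size.
#' @param ... Unused.
#' @return List: `probabilities` (length N), `alpha` (N x V x T),
#'   `beta` (N x V).
#' @export
predict.imv_model <- function(object, windows, chunk = 256L, ...) {
  x <- if (inherits(windows, "window_tensor")) windows$data else windows
  if (dim(x)[3] != attr(object$params, "V"))
    stop_contract("variable count mismatch with training")
  N <- dim(x)[1]
  probs <- numeric(N)
  alpha <- array(0, c(N, dim(x)[3], dim(x)[2]))
  beta <- matrix(0, N, dim(x)[3])
  for (start in seq(1L, N, by = chunk)) {
    sel <- start:min(start + chunk - 1L, N)
    fwd <- imv_forward_batch(object$params, x[sel, , , drop = FALSE])
    probs[sel] <- fwd$prob
    alpha[sel, , ] <- fwd$alpha
    beta[sel, ] <- fwd$beta
  }
  list(probabilities = probs, alpha = alpha, beta = beta)
}

#' Save / load IMV-LSTM weights as portable JSON
#'
#' @param model An `imv_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_imv <- function(model, path) {
  pl <- lapply(model$params, function(p)
    list(dim = dim(p) %||% length(p), data = as.vector(p)))
  obj <- list(V = attr(model$params, "V"), d = attr(model$params, "d"),
              variables = model$variables, params = pl,
              hyper = unclass(model$hyper), best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_imv
#' @export
load_imv <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    arr <- as.numeric(p$data)
    if (length(p$dim) > 1L) dim(arr) <- p$dim
    arr
  })
  attr(params, "V") <- obj$V
  attr(params, "d") <- obj$d
  structure(list(params = params, hyper = do.call(imv_hyperparams,
                                                  obj$hyper[c("d", "epochs", "batch", "lr", "patience", "seed", "threshold", "pos_weight")]),
                 variables = obj$variables, history = NULL,
                 best_epoch = obj$best_epoch),
            class = "imv_model")
}
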