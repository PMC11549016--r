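# Network layers: embedding, GRU, 1-D convolution blocks, multi-head
# self-attention, pooling and the softmax classifier. Every layer has a
# batched forward pass that caches what its backward pass needs; gradients
# are verified against finite differences in the test suite.
#
# Batched sequence data is represented as a list over time steps of
# B x d matrices; attention operates on a stacked (B*n) x d matrix whose
# rows are grouped by example (row (b-1)*n + t).

#' Logistic sigmoid
#' @param x numeric array.
#' @return 1 / (1 + exp(-x)), elementwise.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
relu <- function(x) x * (x > 0)

#' @noRd
softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  e <- exp(S - mx)
  e / rowSums(e)
}

#' @noRd
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Embedding -------------------------------------------------------------------

#' Embed an integer-encoded sequence
#'
#' Row i of the result is the embedding-table row selected by `codes[i]`,
#' plus (optionally) the sinusoidal positional-encoding row for position i.
#'
#' @param codes integer vector of base codes in 0..3.
#' @param embedding a 4 x d embedding table.
#' @param use_pe add the positional encoding.
#' @param pe_base positional-encoding frequency base.
#' @return An L x d matrix.
#' @export
embed_sequence <- function(codes, embedding, use_pe = TRUE, pe_base = 10000L) {
  if (any(codes < 0 | codes > 3)) stop("codes must lie in 0..3")
  out <- embedding[codes + 1L, , drop = FALSE]
  if (use_pe) out <- out + positional_encoding(length(codes), ncol(embedding),
                                               pe_base)
  out
}

# GRU -------------------------------------------------------------------------

# The three gate projections are fused: input projections for all time
# steps are computed in one matrix product up front, and weight gradients
# are accumulated as stacked products at the end of the backward sweep, so
# the per-step work is a single H x 3H recurrent product plus elementwise
# gate arithmetic.

#' @noRd
gru_dir_forward <- function(X, p, reverse = FALSE) {
  L <- length(X)
  B <- nrow(X[[1]])
  H <- ncol(p$Whh)
  iz <- seq_len(H); ir <- H + iz; ic <- 2 * H + iz
  Wh <- cbind(p$Wzh, p$Wrh, p$Whh)
  Xall <- do.call(rbind, X)  # rows grouped by time step
  XP <- add_bias(Xall %*% cbind(p$Wzx, p$Wrx, p$Whx),
                 c(p$bzh + p$bzx, p$brh + p$brx, p$bhx))
  order_t <- if (reverse) L:1 else 1:L
  h_list <- vector("list", L)
  cache <- vector("list", L)
  h_prev <- matrix(0, B, H)
  for (t in order_t) {
    xp <- XP[(t - 1) * B + seq_len(B), , drop = FALSE]
    hp <- h_prev %*% Wh
    z <- sigmoid(xp[, iz, drop = FALSE] + hp[, iz, drop = FALSE])
    r <- sigmoid(xp[, ir, drop = FALSE] + hp[, ir, drop = FALSE])
    a <- add_bias(hp[, ic, drop = FALSE], p$bhh)
    cc <- tanh(xp[, ic, drop = FALSE] + r * a)
    h <- (1 - z) * h_prev + z * cc
    cache[[t]] <- list(h_prev = h_prev, z = z, r = r, a = a, c = cc)
    h_list[[t]] <- h
    h_prev <- h
  }
  list(h = h_list, cache = cache, order_t = order_t, Xall = Xall, B = B)
}

#' @noRd
gru_dir_backward <- function(dH, fwd, p) {
  L <- length(dH)
  B <- fwd$B
  H <- ncol(p$Whh)
  Wh <- cbind(p$Wzh, p$Wrh, p$Whh)
  Wx <- cbind(p$Wzx, p$Wrx, p$Whx)
  Dz <- matrix(0, B * L, H)  # d pre-activation of the update gate
  Dr <- matrix(0, B * L, H)  # ... of the reset gate
  Dc <- matrix(0, B * L, H)  # ... of the candidate
  Da <- matrix(0, B * L, H)  # d of the recurrent candidate term
  Hprev <- matrix(0, B * L, H)
  dh_carry <- 0
  for (t in rev(fwd$order_t)) {
    cc <- fwd$cache[[t]]
    rows <- (t - 1) * B + seq_len(B)
    dh <- dH[[t]] + dh_carry
    dz <- dh * (cc$c - cc$h_prev)
    dpre_c <- dh * cc$z * (1 - cc$c^2)
    da <- dpre_c * cc$r
    dpre_r <- dpre_c * cc$a * cc$r * (1 - cc$r)
    dpre_z <- dz * cc$z * (1 - cc$z)
    dh_carry <- dh * (1 - cc$z) + cbind(dpre_z, dpre_r, da) %*% t(Wh)
    Dz[rows, ] <- dpre_z
    Dr[rows, ] <- dpre_r
    Dc[rows, ] <- dpre_c
    Da[rows, ] <- da
    Hprev[rows, ] <- cc$h_prev
  }
  Gx <- cbind(Dz, Dr, Dc)
  dWx <- crossprod(fwd$Xall, Gx)
  dWh <- crossprod(Hprev, cbind(Dz, Dr, Da))
  iz <- seq_len(H); ir <- H + iz; ic <- 2 * H + iz
  sz <- colSums(Dz); sr <- colSums(Dr)
  g <- list(Wzh = dWh[, iz, drop = FALSE], Wzx = dWx[, iz, drop = FALSE],
            bzh = sz, bzx = sz,
            Wrh = dWh[, ir, drop = FALSE], Wrx = dWx[, ir, drop = FALSE],
            brh = sr, brx = sr,
            Whx = dWx[, ic, drop = FALSE], Whh = dWh[, ic, drop = FALSE],
            bhx = colSums(Dc), bhh = colSums(Da))
  g <- g[names(p)]
  dXall <- Gx %*% t(Wx)
  dX <- lapply(seq_len(L), function(t) {
    dXall[(t - 1) * B + seq_len(B), , drop = FALSE]
  })
  list(dX = dX, grads = g)
}

#' @noRd
bigru_forward <- function(X, params) {
  f <- gru_dir_forward(X, params$f, reverse = FALSE)
  if (!is.null(params$b)) {
    b <- gru_dir_forward(X, params$b, reverse = TRUE)
    out <- mapply(cbind, f$h, b$h, SIMPLIFY = FALSE)
  } else {
    b <- NULL
    out <- f$h
  }
  list(out = out, f = f, b = b)
}

#' @noRd
bigru_backward <- function(dOut, fw, params) {
  H <- ncol(params$f$Whh)
  if (!is.null(params$b)) {
    dHf <- lapply(dOut, function(m) m[, 1:H, drop = FALSE])
    dHb <- lapply(dOut, function(m) m[, H + (1:H), drop = FALSE])
    bf <- gru_dir_backward(dHf, fw$f, params$f)
    bb <- gru_dir_backward(dHb, fw$b, params$b)
    dX <- mapply(`+`, bf$dX, bb$dX, SIMPLIFY = FALSE)
    list(dX = dX, grads = list(f = bf$grads, b = bb$grads))
  } else {
    bf <- gru_dir_backward(dOut, fw$f, params$f)
    list(dX = bf$dX, grads = list(f = bf$grads))
  }
}

#' Bidirectional GRU over a single sequence
#'
#' The forward recurrence runs left to right; the backward recurrence runs
#' right to left and reads the following hidden state. Output row t
#' concatenates the forward and backward hidden states at t. Update and
#' reset gates are logistic; the candidate state is tanh of the input map
#' plus the reset-gated recurrent map.
#'
#' @param X an L x d input matrix (one row per position).
#' @param params GRU parameters: a list with element `f` (and `b` when
#'   bidirectional), each holding `Wzh, Wzx, bzh, bzx, Wrh, Wrx, brh, brx,
#'   Whx, Whh, bhx, bhh` (see [init_network_params()]).
#' @return An L x H or L x 2H matrix of hidden states.
#' @export
bigru <- function(X, params) {
  if (!all(is.finite(X))) stop("non-finite input to bigru")
  Xl <- lapply(seq_len(nrow(X)), function(t) X[t, , drop = FALSE])
  fw <- bigru_forward(Xl, params)
  do.call(rbind, fw$out)
}

# Multi-head self-attention ----------------------------------------------------

# Per-head Q/K/V projections are fused into a single product with the
# column-bound projection matrix; only the per-example score softmax and
# value mixing remain as small loops.

#' @noRd
mha_forward <- function(M, p, n) {
  B <- nrow(M) / n
  h <- length(p$heads)
  d_k <- ncol(p$heads[[1]]$Wq)
  Wqkv <- do.call(cbind, lapply(p$heads, function(hp) {
    cbind(hp$Wq, hp$Wk, hp$Wv)
  }))
  QKV <- M %*% Wqkv
  Hcat <- matrix(0, nrow(M), h * d_k)
  A <- vector("list", h)
  sq <- sqrt(d_k)
  for (i in seq_len(h)) {
    off <- (i - 1) * 3 * d_k
    qc <- off + seq_len(d_k); kc <- off + d_k + seq_len(d_k)
    vc <- off + 2 * d_k + seq_len(d_k)
    cols <- (i - 1) * d_k + seq_len(d_k)
    A[[i]] <- vector("list", B)
    for (b in seq_len(B)) {
      idx <- (b - 1) * n + seq_len(n)
      S <- tcrossprod(QKV[idx, qc, drop = FALSE],
                      QKV[idx, kc, drop = FALSE]) / sq
      Ab <- softmax_rows(S)
      A[[i]][[b]] <- Ab
      Hcat[idx, cols] <- Ab %*% QKV[idx, vc, drop = FALSE]
    }
  }
  out <- Hcat %*% p$Wo
  list(out = out, cache = list(M = M, QKV = QKV, Wqkv = Wqkv, A = A,
                               Hcat = Hcat, n = n, B = B, d_k = d_k))
}

#' @noRd
mha_backward <- function(dOut, fw, p) {
  cc <- fw$cache
  h <- length(p$heads)
  d_k <- cc$d_k
  n <- cc$n
  B <- cc$B
  g <- list(heads = vector("list", h), Wo = crossprod(cc$Hcat, dOut))
  dHcat <- dOut %*% t(p$Wo)
  dQKV <- matrix(0, nrow(cc$M), ncol(cc$QKV))
  sq <- sqrt(d_k)
  for (i in seq_len(h)) {
    off <- (i - 1) * 3 * d_k
    qc <- off + seq_len(d_k); kc <- off + d_k + seq_len(d_k)
    vc <- off + 2 * d_k + seq_len(d_k)
    cols <- (i - 1) * d_k + seq_len(d_k)
    for (b in seq_len(B)) {
      idx <- (b - 1) * n + seq_len(n)
      Ab <- cc$A[[i]][[b]]
      dHead <- dHcat[idx, cols, drop = FALSE]
      dQKV[idx, vc] <- crossprod(Ab, dHead)
      dA <- tcrossprod(dHead, cc$QKV[idx, vc, drop = FALSE])
      dS <- Ab * (dA - rowSums(dA * Ab)) / sq
      dQKV[idx, qc] <- dS %*% cc$QKV[idx, kc, drop = FALSE]
      dQKV[idx, kc] <- crossprod(dS, cc$QKV[idx, qc, drop = FALSE])
    }
  }
  dWqkv <- crossprod(cc$M, dQKV)
  for (i in seq_len(h)) {
    off <- (i - 1) * 3 * d_k
    g$heads[[i]] <- list(
      Wq = dWqkv[, off + seq_len(d_k), drop = FALSE],
      Wk = dWqkv[, off + d_k + seq_len(d_k), drop = FALSE],
      Wv = dWqkv[, off + 2 * d_k + seq_len(d_k), drop = FALSE]
    )
  }
  dM <- dQKV %*% t(cc$Wqkv)
  list(dM = dM, grads = g)
}

#' Multi-head scaled dot-product self-attention
#'
#' Per head i: Q, K, V are linear projections of the input; attention
#' weights are the row-softmax of Q K' / sqrt(d_k); the head output is the
#' weighted sum of V rows. Head outputs are concatenated and reprojected by
#' `Wo`. No masking is applied.
#'
#' @param X an n x d input matrix.
#' @param params attention parameters: `heads` (a list of per-head `Wq`,
#'   `Wk`, `Wv`, each d x d_k) and `Wo` ((h * d_k) x d_out).
#' @return An n x d_out matrix.
#' @export
multihead_attention <- function(X, params) {
  d_in <- nrow(params$heads[[1]]$Wq)
  if (ncol(X) != d_in) stop("input width does not match attention projections")
  mha_forward(X, params, n = nrow(X))$out
}

#' Attention weight matrices for inspection
#'
#' Returns the per-head row-softmax attention matrices for a single input,
#' each row summing to 1.
#'
#' @inheritParams multihead_attention
#' @return A list (one per head) of n x n attention-weight matrices.
#' @export
attention_weights <- function(X, params) {
  fw <- mha_forward(X, params, n = nrow(X))
  lapply(fw$cache$A, function(per_ex) per_ex[[1]])
}

# 1-D convolution block --------------------------------------------------------

#' @noRd
pool1d_forward <- function(Yarr, w) {
  B <- dim(Yarr)[1]; P <- dim(Yarr)[2]; C <- dim(Yarr)[3]
  Pp <- floor(P / w)
  if (Pp < 1) stop("spatial length ", P, " shorter than pool width ", w)
  out <- array(0, c(B, Pp, C))
  amax <- array(0L, c(B, Pp, C))
  for (q in seq_len(Pp)) {
    win <- (q - 1) * w + seq_len(w)
    best <- matrix(Yarr[, win[1], ], nrow = B)
    pos <- matrix(win[1], B, C)
    for (j in win[-1]) {
      mj <- matrix(Yarr[, j, ], nrow = B)
      upd <- mj > best
      best[upd] <- mj[upd]
      pos[upd] <- j
    }
    out[, q, ] <- best
    amax[, q, ] <- pos
  }
  list(out = out, amax = amax, P = P)
}

#' @noRd
pool1d_backward <- function(dOut, amax, P) {
  B <- dim(dOut)[1]; Pp <- dim(dOut)[2]; C <- dim(dOut)[3]
  dY <- array(0, c(B, P, C))
  bvec <- rep(seq_len(B), times = C)
  cvec <- rep(seq_len(C), each = B)
  for (q in seq_len(Pp)) {
    posv <- as.vector(matrix(amax[, q, ], nrow = B))
    lin <- bvec + (posv - 1) * B + (cvec - 1) * B * P
    dY[lin] <- dY[lin] + as.vector(matrix(dOut[, q, ], nrow = B))
  }
  dY
}

#' @noRd
conv_block_forward <- function(X, blk, padding, pool_width) {
  B <- dim(X)[1]; L <- dim(X)[2]; C_in <- dim(X)[3]
  kw <- dim(blk$W)[1]; C_out <- dim(blk$W)[3]
  Lp <- L + 2 * padding
  if (kw > Lp) stop("kernel width ", kw, " exceeds padded length ", Lp)
  P <- Lp - kw + 1
  Xp <- array(0, c(B, Lp, C_in))
  Xp[, padding + seq_len(L), ] <- X
  Xcol <- matrix(0, B * P, kw * C_in)
  for (c_ in seq_len(C_in)) {
    for (j in seq_len(kw)) {
      Xcol[, (c_ - 1) * kw + j] <-
        as.vector(matrix(Xp[, j:(j + P - 1), c_], nrow = B))
    }
  }
  Wmat <- matrix(blk$W, nrow = kw * C_in)
  Ypre <- add_bias(Xcol %*% Wmat, blk$b)
  mask <- Ypre > 0
  Yarr <- array(Ypre * mask, c(B, P, C_out))
  pl <- pool1d_forward(Yarr, pool_width)
  list(out = pl$out,
       cache = list(Xcol = Xcol, mask = mask, amax = pl$amax,
                    B = B, L = L, P = P, C_in = C_in, C_out = C_out,
                    kw = kw, padding = padding, Lp = Lp))
}

#' @noRd
conv_block_backward <- function(dOut, fw, blk) {
  cc <- fw$cache
  dYarr <- pool1d_backward(dOut, cc$amax, cc$P)
  dY <- matrix(dYarr, nrow = cc$B * cc$P) * cc$mask
  g <- list(W = array(crossprod(cc$Xcol, dY), dim = dim(blk$W)),
            b = colSums(dY))
  Wmat <- matrix(blk$W, nrow = cc$kw * cc$C_in)
  dXcol <- dY %*% t(Wmat)
  dXp <- array(0, c(cc$B, cc$Lp, cc$C_in))
  for (c_ in seq_len(cc$C_in)) {
    for (j in seq_len(cc$kw)) {
      idx <- j:(j + cc$P - 1)
      dXp[, idx, c_] <- matrix(dXp[, idx, c_], nrow = cc$B) +
        matrix(dXcol[, (c_ - 1) * cc$kw + j], nrow = cc$B)
    }
  }
  dX <- dXp[, cc$padding + seq_len(cc$L), , drop = FALSE]
  list(dX = dX, grads = g)
}

#' One convolution block: conv -> ReLU -> max-pool
#'
#' 1-D convolution with stride 1 and symmetric zero padding, ReLU
#' activation, then a non-overlapping max-pool (remainder positions are
#' dropped). Three stacked blocks plus one extra max-pool form the
#' convolutional module of path 2.
#'
#' @param x an L x C_in matrix (positions by channels).
#' @param filters a kernel x C_in x C_out weight array.
#' @param bias length-C_out bias vector.
#' @param padding symmetric zero padding in cells.
#' @param pool_width non-overlapping max-pool width.
#' @return A floor((L + 2*padding - kernel + 1) / pool_width) x C_out matrix.
#' @export
conv_block <- function(x, filters, bias, padding = 2L, pool_width = 2L) {
  X <- array(x, c(1, nrow(x), ncol(x)))
  fw <- conv_block_forward(X, list(W = filters, b = bias), padding, pool_width)
  matrix(fw$out, nrow = dim(fw$out)[2], ncol = dim(fw$out)[3])
}

# Pooling and classifier --------------------------------------------------------

#' Reduce a position-wise matrix to a path summary vector
#'
#' @param X an n x d matrix (n >= 1).
#' @param mode `"mean"` (default) or `"max"` over rows.
#' @return A length-d vector.
#' @export
pool_path <- function(X, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (is.null(dim(X)) || nrow(X) < 1) stop("pool_path requires a non-empty matrix")
  if (mode == "mean") colMeans(X) else apply(X, 2, max)
}

#' @noRd
pool_stack_forward <- function(M, n, mode) {
  B <- nrow(M) / n
  grp <- rep(seq_len(B), each = n)
  if (mode == "mean") {
    v <- rowsum(M, grp) / n
    list(v = v, cache = list(n = n, B = B, mode = mode))
  } else {
    v <- matrix(0, B, ncol(M))
    amax <- matrix(0L, B, ncol(M))
    for (b in seq_len(B)) {
      idx <- (b - 1) * n + seq_len(n)
      sub <- M[idx, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      v[b, ] <- sub[cbind(am, seq_len(ncol(M)))]
      amax[b, ] <- am
    }
    list(v = v, cache = list(n = n, B = B, mode = mode, amax = amax))
  }
}

#' @noRd
pool_stack_backward <- function(dV, cache) {
  n <- cache$n; B <- cache$B
  if (cache$mode == "mean") {
    dV[rep(seq_len(B), each = n), , drop = FALSE] / n
  } else {
    dM <- matrix(0, B * n, ncol(dV))
    for (b in seq_len(B)) {
      rows <- (b - 1) * n + cache$amax[b, ]
      dM[cbind(rows, seq_len(ncol(dV)))] <- dV[b, ]
    }
    dM
  }
}

#' @noRd
classifier_forward <- function(v, p, dropout = 0, training = FALSE) {
  pre1 <- add_bias(v %*% p$W1, p$b1)
  h1 <- relu(pre1)
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask <- (matrix(stats::runif(length(h1)), nrow(h1), ncol(h1)) < keep) / keep
  } else {
    mask <- NULL
  }
  h1d <- if (is.null(mask)) h1 else h1 * mask
  logits <- add_bias(h1d %*% p$W2, p$b2)
  prob <- softmax_rows(logits)
  list(prob = prob, cache = list(v = v, pre1 = pre1, h1d = h1d, mask = mask))
}

#' @noRd
classifier_backward <- function(dlogits, fw, p) {
  cc <- fw$cache
  g <- list(W1 = NULL, b1 = NULL,
            W2 = crossprod(cc$h1d, dlogits), b2 = colSums(dlogits))
  dh1d <- dlogits %*% t(p$W2)
  dh1 <- if (is.null(cc$mask)) dh1d else dh1d * cc$mask
  dpre1 <- dh1 * (cc$pre1 > 0)
  g$W1 <- crossprod(cc$v, dpre1)
  g$b1 <- colSums(dpre1)
  dv <- dpre1 %*% t(p$W1)
  list(dv = dv, grads = g)
}

#' Two-layer softmax classifier
#'
#' y = Softmax(W2 . ReLU(W1 x + b1) + b2). Evaluation-mode (no dropout).
#'
#' @param v input feature vector (the concatenated path summaries).
#' @param params list with `W1`, `b1`, `W2`, `b2`.
#' @return A length-2 probability vector (negative, positive), summing to 1.
#' @export
classify <- function(v, params) {
  if (length(v) != nrow(params$W1)) stop("input width mismatch: expected ",
                                         nrow(params$W1), ", got ", length(v))
  fw <- classifier_forward(matrix(v, nrow = 1), params)
  stats::setNames(as.vector(fw$prob), c("neg", "pos"))
}
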