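# The dual-path model: batched end-to-end forward pass, backpropagation,
# prediction, and checkpoint I/O.

#' @noRd
build_path1_input <- function(codes, params, config) {
  B <- nrow(codes); L <- ncol(codes)
  d_in <- path1_input_dim(config)
  pe <- if (config$use_pe) positional_encoding(L, d_in, config$pe_base) else NULL
  X <- vector("list", L)
  for (t in seq_len(L)) {
    if (config$path1_scheme == "integer") {
      xt <- params$embed$E[codes[, t] + 1L, , drop = FALSE]
    } else {
      xt <- matrix(0, B, 4L)
      xt[cbind(seq_len(B), codes[, t] + 1L)] <- 1
    }
    if (!is.null(pe)) xt <- add_bias(xt, pe[t, ])
    X[[t]] <- xt
  }
  X
}

#' @noRd
stack_steps <- function(X) {
  L <- length(X); B <- nrow(X[[1]])
  M <- matrix(0, B * L, ncol(X[[1]]))
  for (t in seq_len(L)) M[seq(t, B * L, by = L), ] <- X[[t]]
  M
}

#' @noRd
unstack_steps <- function(M, L) {
  B <- nrow(M) / L
  lapply(seq_len(L), function(t) M[seq(t, B * L, by = L), , drop = FALSE])
}

#' @noRd
stack_conv <- function(arr) {
  # B x P x C array -> (B*P) x C matrix, rows grouped by example
  P <- dim(arr)[2]; B <- dim(arr)[1]; C <- dim(arr)[3]
  M <- aperm(arr, c(2, 1, 3))
  dim(M) <- c(P * B, C)
  M
}

#' @noRd
unstack_conv <- function(M, B, P) {
  arr <- array(M, c(P, B, ncol(M)))
  aperm(arr, c(2, 1, 3))
}

#' Batched forward pass through the dual-path network
#'
#' Internal engine behind [network_forward()], [predict_proba()] and
#' training. `p1_override` / `p2_override` replace the path-1 embedded input
#' (a list over positions of B x d matrices) or the path-2 feature matrix —
#' used by the fast-gradient attack, which perturbs exactly these tensors.
#'
#' @param codes B x L integer code matrix (path 1), or NULL.
#' @param pfeat B x D PseKNC feature matrix (path 2), or NULL.
#' @param params,config network parameters and configuration.
#' @param training enable dropout.
#' @param p1_override,p2_override optional input overrides.
#' @return list with `prob` (B x 2) and `cache` for the backward pass.
#' @noRd
forward_batch <- function(codes, pfeat, params, config, training = FALSE,
                          p1_override = NULL, p2_override = NULL) {
  cache <- list(config = config)
  vs <- list()

  if (config$use_path1) {
    X <- if (!is.null(p1_override)) p1_override else
      build_path1_input(codes, params, config)
    L <- length(X)
    gru <- bigru_forward(X, params$gru)
    M1 <- stack_steps(gru$out)
    if (config$use_attention) {
      att1 <- mha_forward(M1, params$att1, n = L)
      M1a <- att1$out
    } else {
      att1 <- NULL
      M1a <- M1
    }
    pl1 <- pool_stack_forward(M1a, n = L, mode = config$pool_mode)
    vs$v1 <- pl1$v
    cache$p1 <- list(X = X, L = L, gru = gru, att1 = att1, pl1 = pl1,
                     codes = codes)
  }

  if (config$use_path2) {
    x2 <- if (!is.null(p2_override)) p2_override else pfeat
    B <- nrow(x2); D <- ncol(x2)
    arr <- array(x2, c(B, D, 1L))
    blocks <- vector("list", 3)
    for (i in 1:3) {
      blocks[[i]] <- conv_block_forward(arr, params$conv[[i]],
                                        config$conv_padding, config$pool_width)
      arr <- blocks[[i]]$out
    }
    fin <- pool1d_forward(arr, config$pool_width)
    P <- dim(fin$out)[2]
    M2 <- stack_conv(fin$out)
    if (config$use_attention) {
      M2b <- add_bias(M2 %*% params$bridge$W, params$bridge$b)
      att2 <- mha_forward(M2b, params$att2, n = P)
      M2a <- att2$out
    } else {
      att2 <- NULL
      M2a <- M2
    }
    pl2 <- pool_stack_forward(M2a, n = P, mode = config$pool_mode)
    vs$v2 <- pl2$v
    cache$p2 <- list(x2 = x2, B = B, D = D, blocks = blocks, fin = fin,
                     P = P, M2 = M2, att2 = att2, pl2 = pl2,
                     pre_fin_dim = dim(blocks[[3]]$out))
  }

  v <- do.call(cbind, vs)
  cls <- classifier_forward(v, params$classifier, config$dropout, training)
  cache$cls <- cls
  cache$v1_width <- if (config$use_path1) ncol(vs$v1) else 0L
  list(prob = cls$prob, cache = cache)
}

#' Batched backward pass
#'
#' @param dlogits B x 2 gradient of the loss w.r.t. the classifier logits.
#' @param fw the forward cache from `forward_batch`.
#' @return list with `grads` (mirroring the parameter tree), `d_p1X`
#'   (gradient w.r.t. the embedded path-1 input, list over positions) and
#'   `d_pfeat` (gradient w.r.t. the PseKNC features).
#' @noRd
backward_batch <- function(dlogits, fw, params, config) {
  cb <- classifier_backward(dlogits, fw$cache$cls, params$classifier)
  g <- list()
  d_p1X <- NULL
  d_pfeat <- NULL
  w1 <- fw$cache$v1_width

  if (config$use_path1) {
    p1 <- fw$cache$p1
    dv1 <- cb$dv[, seq_len(w1), drop = FALSE]
    dM1a <- pool_stack_backward(dv1, p1$pl1$cache)
    if (config$use_attention) {
      ab <- mha_backward(dM1a, p1$att1, params$att1)
      g$att1 <- ab$grads
      dM1 <- ab$dM
    } else {
      dM1 <- dM1a
    }
    dG <- unstack_steps(dM1, p1$L)
    gb <- bigru_backward(dG, p1$gru, params$gru)
    g$gru <- gb$grads
    d_p1X <- gb$dX
    if (config$path1_scheme == "integer") {
      dE <- matrix(0, 4L, ncol(params$embed$E))
      for (t in seq_len(p1$L)) {
        rs <- rowsum(d_p1X[[t]], group = p1$codes[, t])
        rows <- as.integer(rownames(rs)) + 1L
        dE[rows, ] <- dE[rows, ] + rs
      }
      g$embed <- list(E = dE)
    }
  }

  if (config$use_path2) {
    p2 <- fw$cache$p2
    dv2 <- cb$dv[, w1 + seq_len(ncol(cb$dv) - w1), drop = FALSE]
    dM2a <- pool_stack_backward(dv2, p2$pl2$cache)
    if (config$use_attention) {
      ab2 <- mha_backward(dM2a, p2$att2, params$att2)
      g$att2 <- ab2$grads
      dM2b <- ab2$dM
      g$bridge <- list(W = crossprod(p2$M2, dM2b), b = colSums(dM2b))
      dM2 <- dM2b %*% t(params$bridge$W)
    } else {
      dM2 <- dM2a
    }
    darr <- unstack_conv(dM2, p2$B, p2$P)
    darr <- pool1d_backward(darr, p2$fin$amax, p2$pre_fin_dim[2])
    g$conv <- vector("list", 3)
    for (i in 3:1) {
      bb <- conv_block_backward(darr, p2$blocks[[i]], params$conv[[i]])
      g$conv[[i]] <- bb$grads
      darr <- bb$dX
    }
    d_pfeat <- matrix(darr, nrow = p2$B)
  }

  g$classifier <- cb$grads
  # order the gradient tree to mirror the parameter tree exactly
  g <- g[names(params)]
  class(g) <- "network_params"
  list(grads = g, d_p1X = d_p1X, d_pfeat = d_pfeat)
}

#' Forward pass for a single sequence
#'
#' Runs the full dual-path network in evaluation mode (dropout off) and
#' returns the predicted probability that the central cytidine is
#' ac4C-modified. Path 1 consumes the integer-encoded sequence; path 2
#' consumes its PseKNC feature vector (computed from `record` when `pfeat`
#' is not supplied).
#'
#' @param record a sequence string, or a one-row record `data.frame`.
#' @param params network parameters (see [init_network_params()]).
#' @param config a [network_config()].
#' @param pfeat optional precomputed PseKNC vector (length 4^k + 2).
#' @return The probability of ac4C modification, in \[0, 1\].
#' @export
network_forward <- function(record, params, config, pfeat = NULL) {
  seq_ <- if (is.data.frame(record)) record$seq[1] else record
  codes <- if (config$use_path1) {
    matrix(integer_encode(seq_), nrow = 1)
  } else NULL
  pf <- if (config$use_path2) {
    if (is.null(pfeat)) pfeat <- pseknc(seq_, k = config$kmer_k)$F
    matrix(pfeat, nrow = 1)
  } else NULL
  fw <- forward_batch(codes, pf, params, config, training = FALSE)
  unname(fw$prob[1, 2])
}

#' @noRd
scale_features <- function(x, center, scale) {
  (x - rep(center, each = nrow(x))) / rep(scale, each = nrow(x))
}

#' @noRd
apply_feat_scaling <- function(model, pfeat) {
  if (!is.null(pfeat) && !is.null(model$feat_center)) {
    pfeat <- scale_features(pfeat, model$feat_center, model$feat_scale)
  }
  pfeat
}

#' Predict ac4C probabilities for a set of records
#'
#' @param model a checkpoint (from [train_fold()] / [load_checkpoint()]) or a
#'   list with elements `params` and `config`.
#' @param records a record `data.frame`.
#' @param batch_size evaluation batch size.
#' @return Numeric vector of P(ac4C) aligned to `records`.
#' @export
predict_proba <- function(model, records, batch_size = 256L) {
  params <- model$params; config <- model$config
  n <- nrow(records)
  codes <- if (config$use_path1) encode_records(records, "integer") else NULL
  pfeat <- if (config$use_path2) {
    apply_feat_scaling(model, encode_records(records, "pseknc",
                                             k = config$kmer_k))
  } else NULL
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- forward_batch(if (is.null(codes)) NULL else codes[idx, , drop = FALSE],
                        if (is.null(pfeat)) NULL else pfeat[idx, , drop = FALSE],
                        params, config, training = FALSE)
    out[idx] <- fw$prob[, 2]
  }
  out
}

# Checkpoints -------------------------------------------------------------------

CHECKPOINT_VERSION <- "1.0"

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the network parameters,
#' the architecture and training configurations, the seed, and training
#' metadata, under a versioned format tag.
#'
#' @param checkpoint a list with at least `params` and `config` (as produced
#'   by [train_fold()]).
#' @param path file path.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   checkpoint list.
#' @export
save_checkpoint <- function(checkpoint, path) {
  checkpoint$format_version <- CHECKPOINT_VERSION
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format_version, CHECKPOINT_VERSION)) {
    stop("unsupported checkpoint format version: ", ck$format_version)
  }
  ck
}
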