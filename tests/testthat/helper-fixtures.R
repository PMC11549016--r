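# Shared fixtures and independent oracles used across the suite.

# A deliberately small architecture for fast exact tests.
tiny_config <- function(...) {
  network_config(d_model = 8, gru_hidden = 6, heads = 2,
                 conv_channels = c(3, 4, 5), classifier_hidden = 7,
                 dropout = 0, ...)
}

# The reduced architecture used for the synthetic-benchmark learning runs.
small_config <- function(...) {
  network_config(d_model = 32, gru_hidden = 32, heads = 4,
                 conv_channels = c(8, 16, 32), classifier_hidden = 64,
                 dropout = 0.2, ...)
}

random_records <- function(n, L, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("r%03d", seq_len(n)),
    seq = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    }, character(1)),
    label = rep_len(c(1L, 0L), n),
    stringsAsFactors = FALSE
  )
}

# --- gradient-test utilities -------------------------------------------------

leaf_paths <- function(tree, prefix = list()) {
  if (is.list(tree)) {
    keys <- if (is.null(names(tree))) seq_along(tree) else names(tree)
    out <- list()
    for (k in keys) out <- c(out, leaf_paths(tree[[k]], c(prefix, k)))
    out
  } else list(prefix)
}

tree_get <- function(tree, pth) {
  for (k in pth) tree <- tree[[k]]
  tree
}

tree_set <- function(tree, pth, i, val) {
  if (length(pth) == 0) {
    tree[i] <- val
    return(tree)
  }
  tree[[pth[[1]]]] <- tree_set(tree[[pth[[1]]]], pth[-1], i, val)
  tree
}

# --- independent oracles -----------------------------------------------------

# O(n^2) pairwise AUROC with half-credit for ties.
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Trapezoidal integration of the empirical ROC curve.
auroc_trapezoid <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 1) / np,
                     numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 0) / nn,
                     numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Brute-force sliding-dot-product 1-D convolution -> ReLU -> max-pool.
conv_block_oracle <- function(x, W, b, padding, pool_width) {
  L <- nrow(x); C_in <- ncol(x); kw <- dim(W)[1]; C_out <- dim(W)[3]
  xp <- rbind(matrix(0, padding, C_in), x, matrix(0, padding, C_in))
  P <- nrow(xp) - kw + 1
  y <- matrix(0, P, C_out)
  for (p in seq_len(P)) for (o in seq_len(C_out)) {
    acc <- b[o]
    for (j in seq_len(kw)) for (c_ in seq_len(C_in)) {
      acc <- acc + xp[p + j - 1, c_] * W[j, c_, o]
    }
    y[p, o] <- max(acc, 0)
  }
  Pp <- floor(P / pool_width)
  out <- matrix(0, Pp, C_out)
  for (q in seq_len(Pp)) {
    win <- (q - 1) * pool_width + seq_len(pool_width)
    out[q, ] <- apply(y[win, , drop = FALSE], 2, max)
  }
  out
}

# Brute-force greedy redundancy filter over all kept pairs.
redundancy_oracle <- function(seqs, threshold) {
  kept <- character(0)
  for (s in seqs) {
    ok <- TRUE
    for (k in kept) {
      id <- mean(strsplit(s, "")[[1]] == strsplit(k, "")[[1]])
      if (id >= threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, s)
  }
  kept
}

# Brute-force substring k-mer tally.
kmer_oracle <- function(seq, k) {
  out <- list()
  for (i in seq_len(nchar(seq) - k + 1)) {
    m <- substr(seq, i, i + k - 1)
    out[[m]] <- (out[[m]] %||% 0) + 1
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
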