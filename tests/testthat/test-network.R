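test_that("embedding lookup adds positional encoding and is local", {
  E0 <- matrix(0, 4, 6)
  codes <- c(0L, 3L, 2L, 1L)
  expect_equal(embed_sequence(codes, E0, use_pe = TRUE),
               positional_encoding(4, 6))
  set.seed(21)
  E <- matrix(rnorm(24), 4, 6)
  a <- embed_sequence(c(0L, 1L, 2L), E, use_pe = TRUE)
  b <- embed_sequence(c(0L, 3L, 2L), E, use_pe = TRUE)
  expect_equal(a[-2, ], b[-2, ])
  expect_false(isTRUE(all.equal(a[2, ], b[2, ])))
  expect_equal(embed_sequence(2L, E, use_pe = FALSE), E[3, , drop = FALSE])
  expect_error(embed_sequence(4L, E), "0..3")
})

test_that("GRU fixes the zero point and matches a hand-computed step", {
  zero_dir <- function(d, H) {
    list(Wzh = matrix(0, H, H), Wzx = matrix(0, d, H),
         bzh = numeric(H), bzx = numeric(H),
         Wrh = matrix(0, H, H), Wrx = matrix(0, d, H),
         brh = numeric(H), brx = numeric(H),
         Whx = matrix(0, d, H), Whh = matrix(0, H, H),
         bhx = numeric(H), bhh = numeric(H))
  }
  X <- matrix(rnorm(12), 4, 3)
  out <- bigru(X, list(f = zero_dir(3, 2), b = zero_dir(3, 2)))
  expect_equal(out, matrix(0, 4, 4))
  expect_equal(sigmoid(0), 0.5)

  # scalar one-step GRU, hand-evaluated
  p <- zero_dir(1, 1)
  p$Wzx[] <- 0.7; p$bzh[] <- 0.1; p$bzx[] <- 0.2
  p$Wrx[] <- -0.4; p$brh[] <- 0.05; p$brx[] <- 0.05
  p$Whx[] <- 1.3; p$bhx[] <- -0.2; p$bhh[] <- 0.6
  x <- 0.9
  z <- 1 / (1 + exp(-(0.7 * x + 0.1 + 0.2)))
  r <- 1 / (1 + exp(-(-0.4 * x + 0.05 + 0.05)))
  h1 <- z * tanh(1.3 * x - 0.2 + r * 0.6)  # h0 = 0
  out <- bigru(matrix(x, 1, 1), list(f = p))
  expect_equal(out[1, 1], h1, tolerance = 1e-10)
  expect_error(bigru(matrix(NA_real_, 1, 1), list(f = p)), "finite")
})

test_that("backward GRU equals the reversed-input forward GRU", {
  set.seed(22)
  cfg <- tiny_config()
  params <- init_network_params(cfg, seed = 3)
  L <- 7
  X <- matrix(rnorm(L * cfg$d_model), L, cfg$d_model)
  out <- bigru(X, params$gru)
  H <- cfg$gru_hidden
  back_half <- out[, H + (1:H)]
  rev_fwd <- bigru(X[L:1, ], list(f = params$gru$b))
  expect_equal(back_half, rev_fwd[L:1, ], tolerance = 1e-12)
})

test_that("conv block matches the sliding-dot-product oracle", {
  W <- array(c(1, -1, 2), c(3, 1, 1))
  b <- 0
  x <- matrix(c(0.5, -1, 2, 0, 1, -0.5, 3, 1), ncol = 1)
  got <- conv_block(x, W, b, padding = 1, pool_width = 2)
  expect_equal(got, conv_block_oracle(x, W, b, 1, 2))

  expect_equal(conv_block(matrix(0, 8, 1), W, 0, 1, 2), matrix(0, 4, 1))

  set.seed(23)
  W2 <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  b2 <- rnorm(3)
  x2 <- matrix(rnorm(20), 10, 2)
  got2 <- conv_block(x2, W2, b2, padding = 2, pool_width = 2)
  expect_equal(got2, conv_block_oracle(x2, W2, b2, 2, 2), tolerance = 1e-12)
  expect_true(all(got2 >= 0))
  expect_error(conv_block(matrix(1.0, 1, 1), W2, b2, padding = 0), "kernel")
})

test_that("attention handles degenerate inputs and a hand-computed case", {
  set.seed(24)
  d <- 4; dk <- 2
  prm <- list(heads = list(list(Wq = matrix(rnorm(d * dk), d),
                                Wk = matrix(rnorm(d * dk), d),
                                Wv = matrix(rnorm(d * dk), d))),
              Wo = matrix(rnorm(dk * d), dk, d))
  # n = 1: softmax over a single key is 1, output = x Wv Wo
  x1 <- matrix(rnorm(d), 1, d)
  expect_equal(multihead_attention(x1, prm),
               (x1 %*% prm$heads[[1]]$Wv) %*% prm$Wo, tolerance = 1e-12)

  # identical rows give identical outputs
  xr <- matrix(rep(rnorm(d), 3), 3, d, byrow = TRUE)
  outr <- multihead_attention(xr, prm)
  expect_equal(outr[1, ], outr[2, ])
  expect_equal(outr[2, ], outr[3, ])

  # two-row case against direct evaluation of the formula
  X <- matrix(c(0.3, -1, 2, 0.5, 1.2, 0.1, -0.7, 0.9), 2, 4, byrow = TRUE)
  Q <- X %*% prm$heads[[1]]$Wq
  K <- X %*% prm$heads[[1]]$Wk
  V <- X %*% prm$heads[[1]]$Wv
  S <- Q %*% t(K) / sqrt(dk)
  A <- exp(S) / rowSums(exp(S))
  expect_equal(multihead_attention(X, prm), (A %*% V) %*% prm$Wo,
               tolerance = 1e-10)

  expect_error(multihead_attention(matrix(0, 2, 3), prm), "width")
})

test_that("attention weights are row-stochastic and permutation-equivariant", {
  set.seed(25)
  cfg <- tiny_config()
  params <- init_network_params(cfg, seed = 6)
  g <- cfg$gru_hidden * 2
  X <- matrix(rnorm(5 * g), 5, g)
  for (A in attention_weights(X, params$att1)) {
    expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(multihead_attention(X[perm, ], params$att1),
               multihead_attention(X, params$att1)[perm, ], tolerance = 1e-12)
})

test_that("pooling and the classifier satisfy their closed forms", {
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(pool_path(X[1, , drop = FALSE]), X[1, ])
  cst <- matrix(rep(1:4, each = 3), 3, 4)
  expect_equal(pool_path(cst), as.numeric(1:4))
  expect_equal(pool_path(X), colSums(X) / 3)
  expect_equal(pool_path(X, "max"), apply(X, 2, max))
  expect_error(pool_path(X[0, , drop = FALSE]), "non-empty")

  prm <- list(W1 = matrix(0, 3, 2), b1 = c(0, 0),
              W2 = matrix(0, 2, 2), b2 = c(0, 0))
  expect_equal(unname(classify(c(1, 2, 3), prm)), c(0.5, 0.5))
  prm$b2 <- c(0.3, -1.1)
  expect_equal(unname(classify(c(1, 2, 3), prm)),
               exp(prm$b2) / sum(exp(prm$b2)), tolerance = 1e-12)
  set.seed(26)
  prm2 <- list(W1 = matrix(rnorm(6), 3), b1 = rnorm(2),
               W2 = matrix(rnorm(4), 2), b2 = rnorm(2))
  p <- classify(rnorm(3), prm2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(classify(c(1, 2), prm2), "width")
})

test_that("the full forward pass is deterministic, bounded and ablatable", {
  recs <- random_records(1, 21, seed = 27)
  recs$seq <- sub("^(.{10}).", "\\1C", recs$seq)  # central C
  cfg <- tiny_config()
  params <- init_network_params(cfg, seed = 7)
  p1 <- network_forward(recs$seq[1], params, cfg)
  p2 <- network_forward(recs$seq[1], params, cfg)
  expect_identical(p1, p2)
  expect_gte(p1, 0); expect_lte(p1, 1)

  for (variant in list(tiny_config(use_path2 = FALSE),
                       tiny_config(use_path1 = FALSE),
                       tiny_config(use_pe = FALSE),
                       tiny_config(use_attention = FALSE),
                       tiny_config(use_path2 = FALSE,
                                   path1_scheme = "onehot"))) {
    pv <- init_network_params(variant, seed = 8)
    prob <- network_forward(recs$seq[1], pv, variant)
    expect_true(is.finite(prob) && prob >= 0 && prob <= 1)
  }
})

test_that("parameter count is a pure function of the configuration", {
  count_actual <- function(p) {
    s <- 0
    walk <- function(x) {
      if (is.list(x)) lapply(x, walk) else s <<- s + length(x)
    }
    walk(unclass(p))
    s
  }
  for (cfg in list(tiny_config(), tiny_config(use_path2 = FALSE),
                   tiny_config(use_path1 = FALSE),
                   tiny_config(use_attention = FALSE),
                   tiny_config(bidirectional = FALSE),
                   tiny_config(use_path2 = FALSE, path1_scheme = "onehot"))) {
    expect_equal(param_count(cfg), count_actual(init_network_params(cfg)))
  }
  # d_k follows d_model / heads
  expect_equal(network_config()$d_k, 64L)
  # ablated components are absent from the parameter tree
  p1only <- init_network_params(tiny_config(use_path2 = FALSE))
  expect_null(p1only$conv)
  expect_null(p1only$att2)
  p2only <- init_network_params(tiny_config(use_path1 = FALSE))
  expect_null(p2only$gru)
  expect_null(p2only$embed)
})
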