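# Architectural and training configuration objects.

#' Network architecture configuration
#'
#' Single source of truth for the model shape. Defaults reflect the
#' production architecture: embedding width `d_model` 512, bidirectional GRU
#' with 512 hidden units per direction, 8 attention heads (so
#' `d_k = d_v = d_model / heads = 64`), convolution kernel 4 with zero
#' padding 2, channel widths 32/64/128, non-overlapping max-pool of width 2,
#' a 256-unit classifier hidden layer, dropout 0.2 between the classifier
#' layers, and positional-encoding base 10000. Ablation switches select the
#' paths, the path-1 input scheme, the positional encoding, and the
#' attention layers.
#'
#' @param d_model embedding width for path 1 and the path-2 attention bridge.
#' @param gru_hidden GRU hidden width per direction.
#' @param bidirectional run the GRU in both directions.
#' @param heads number of attention heads; must divide `d_model`.
#' @param conv_kernel,conv_padding 1-D convolution kernel width and symmetric
#'   zero padding (in cells).
#' @param conv_channels length-3 integer vector of output channels for the
#'   three convolution blocks.
#' @param pool_width non-overlapping max-pool width.
#' @param classifier_hidden hidden width of the two-layer classifier.
#' @param dropout dropout probability between classifier layers (training
#'   only; evaluation is deterministic).
#' @param pe_base positional-encoding frequency base.
#' @param kmer_k PseKNC k-mer length feeding path 2 (feature width 4^k + 2).
#' @param use_path1,use_path2 enable the recurrent / convolutional path.
#' @param use_pe add positional encoding to the path-1 embedding.
#' @param use_attention apply multi-head self-attention on both paths.
#' @param path1_scheme path-1 input: learned embedding over integer codes, or
#'   raw one-hot rows (width 4) for the encoding ablation.
#' @param pool_mode how each path's position-wise matrix is reduced to a
#'   fixed-size summary vector before concatenation.
#' @return An object of class `network_config`.
#' @export
network_config <- function(d_model = 512L, gru_hidden = 512L,
                           bidirectional = TRUE, heads = 8L,
                           conv_kernel = 4L, conv_padding = 2L,
                           conv_channels = c(32L, 64L, 128L),
                           pool_width = 2L, classifier_hidden = 256L,
                           dropout = 0.2, pe_base = 10000L, kmer_k = 2L,
                           use_path1 = TRUE, use_path2 = TRUE,
                           use_pe = TRUE, use_attention = TRUE,
                           path1_scheme = c("integer", "onehot"),
                           pool_mode = c("mean", "max")) {
  path1_scheme <- match.arg(path1_scheme)
  pool_mode <- match.arg(pool_mode)
  if (d_model %% heads != 0) stop("d_model must be divisible by heads")
  stopifnot(d_model >= 1, gru_hidden >= 1, heads >= 1, conv_kernel >= 1,
            conv_padding >= 0, length(conv_channels) == 3,
            all(conv_channels >= 1), pool_width >= 1, classifier_hidden >= 1,
            dropout >= 0, dropout < 1, kmer_k >= 1,
            use_path1 || use_path2)
  cfg <- list(d_model = as.integer(d_model),
              gru_hidden = as.integer(gru_hidden),
              bidirectional = isTRUE(bidirectional),
              heads = as.integer(heads),
              d_k = as.integer(d_model / heads),
              conv_kernel = as.integer(conv_kernel),
              conv_padding = as.integer(conv_padding),
              conv_channels = as.integer(conv_channels),
              pool_width = as.integer(pool_width),
              classifier_hidden = as.integer(classifier_hidden),
              dropout = dropout, pe_base = as.integer(pe_base),
              kmer_k = as.integer(kmer_k),
              use_path1 = isTRUE(use_path1), use_path2 = isTRUE(use_path2),
              use_pe = isTRUE(use_pe), use_attention = isTRUE(use_attention),
              path1_scheme = path1_scheme, pool_mode = pool_mode)
  class(cfg) <- "network_config"
  cfg
}

#' Training configuration
#'
#' Defaults follow the published protocol where stated (Adam, learning rate
#' 0.001, cross-entropy loss, 10-fold cross-validation); epochs and batch
#' size are declared defaults.
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs training epochs per fold.
#' @param batch_size minibatch size.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed master integer seed; fold f trains from seed + f.
#' @param standardize z-score the path-2 PseKNC features on training-set
#'   statistics (stored in the checkpoint and re-applied at prediction), so
#'   both path summaries reach the classifier on comparable scales.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 50L,
                         batch_size = 64L, folds = 10L, seed = 1L,
                         standardize = TRUE) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, folds >= 2)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 folds = as.integer(folds), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Fast-gradient-method configuration
#'
#' @param epsilon perturbation magnitude (>= 0; the max-norm radius).
#' @param target which inputs receive the perturbation: the path-1 embedding
#'   output, the path-2 PseKNC features, or both (integer codes themselves
#'   are not differentiable, so path 1 is perturbed after embedding).
#' @param mode `"attack-at-test"` perturbs held-out examples at evaluation;
#'   `"adversarial-train"` adds a second loss term on perturbed inputs during
#'   training.
#' @return An object of class `fgm_config`.
#' @export
fgm_config <- function(epsilon = 0.1,
                       target = c("both", "path1-embedding", "path2-features"),
                       mode = c("attack-at-test", "adversarial-train")) {
  stopifnot(epsilon >= 0)
  structure(list(epsilon = epsilon, target = match.arg(target),
                 mode = match.arg(mode)),
            class = "fgm_config")
}

# Derived widths -------------------------------------------------------------

#' @noRd
path1_input_dim <- function(config) {
  if (config$path1_scheme == "integer") config$d_model else 4L
}

#' @noRd
gru_out_dim <- function(config) {
  config$gru_hidden * (1L + config$bidirectional)
}

#' @noRd
path2_out_dim <- function(config) {
  if (config$use_attention) config$d_model else config$conv_channels[3]
}

#' @noRd
classifier_input_dim <- function(config) {
  (if (config$use_path1) gru_out_dim(config) else 0L) +
    (if (config$use_path2) path2_out_dim(config) else 0L)
}

# Parameter initialization ---------------------------------------------------

#' @noRd
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' @noRd
init_gru_direction <- function(d_in, H) {
  list(Wzh = glorot(H, H), Wzx = glorot(d_in, H),
       bzh = numeric(H), bzx = numeric(H),
       Wrh = glorot(H, H), Wrx = glorot(d_in, H),
       brh = numeric(H), brx = numeric(H),
       Whx = glorot(d_in, H), Whh = glorot(H, H),
       bhx = numeric(H), bhh = numeric(H))
}

#' @noRd
init_attention <- function(d_in, d_k, heads) {
  list(heads = lapply(seq_len(heads), function(i) {
    list(Wq = glorot(d_in, d_k), Wk = glorot(d_in, d_k), Wv = glorot(d_in, d_k))
  }),
  Wo = glorot(heads * d_k, d_in))
}

#' Initialize network parameters
#'
#' Weights are Glorot-uniform, biases zero; only the components required by
#' the configuration's ablation switches are constructed (a path-1-only
#' model carries no convolution parameters, and vice versa).
#'
#' @param config a [network_config()].
#' @param pseknc_dim width of the path-2 feature vector (4^k + 2).
#' @param seed integer seed for the initialization draw.
#' @return A nested list of numeric arrays (class `network_params`).
#' @export
init_network_params <- function(config, pseknc_dim = 4^config$kmer_k + 2L,
                                seed = 1L) {
  set.seed(seed)
  p <- list()
  if (config$use_path1) {
    if (config$path1_scheme == "integer") {
      p$embed <- list(E = glorot(4L, config$d_model))
    }
    d_in <- path1_input_dim(config)
    p$gru <- list(f = init_gru_direction(d_in, config$gru_hidden))
    if (config$bidirectional) {
      p$gru$b <- init_gru_direction(d_in, config$gru_hidden)
    }
    if (config$use_attention) {
      p$att1 <- init_attention(gru_out_dim(config), config$d_k, config$heads)
    }
  }
  if (config$use_path2) {
    ch <- c(1L, config$conv_channels)
    p$conv <- lapply(1:3, function(i) {
      fan_in <- config$conv_kernel * ch[i]
      lim <- sqrt(6 / (fan_in + ch[i + 1]))
      list(W = array(stats::runif(config$conv_kernel * ch[i] * ch[i + 1],
                                  -lim, lim),
                     dim = c(config$conv_kernel, ch[i], ch[i + 1])),
           b = numeric(ch[i + 1]))
    })
    if (config$use_attention) {
      p$bridge <- list(W = glorot(config$conv_channels[3], config$d_model),
                       b = numeric(config$d_model))
      p$att2 <- init_attention(config$d_model, config$d_k, config$heads)
    }
  }
  d_cls <- classifier_input_dim(config)
  p$classifier <- list(W1 = glorot(d_cls, config$classifier_hidden),
                       b1 = numeric(config$classifier_hidden),
                       W2 = glorot(config$classifier_hidden, 2L),
                       b2 = numeric(2L))
  class(p) <- "network_params"
  p
}

#' Count trainable parameters
#'
#' A pure function of the configuration (and the path-2 feature width):
#' ablation switches change only the corresponding components.
#'
#' @inheritParams init_network_params
#' @return Integer parameter count.
#' @export
param_count <- function(config, pseknc_dim = 4^config$kmer_k + 2L) {
  H <- config$gru_hidden
  n <- 0
  if (config$use_path1) {
    d_in <- path1_input_dim(config)
    if (config$path1_scheme == "integer") n <- n + 4 * config$d_model
    per_dir <- 3 * (H * H + d_in * H) + 6 * H  # z, r, candidate gates
    n <- n + per_dir * (1 + config$bidirectional)
    if (config$use_attention) {
      g <- gru_out_dim(config)
      n <- n + config$heads * 3 * g * config$d_k + config$heads * config$d_k * g
    }
  }
  if (config$use_path2) {
    ch <- c(1L, config$conv_channels)
    for (i in 1:3) {
      n <- n + config$conv_kernel * ch[i] * ch[i + 1] + ch[i + 1]
    }
    if (config$use_attention) {
      n <- n + config$conv_channels[3] * config$d_model + config$d_model
      n <- n + config$heads * 3 * config$d_model * config$d_k +
        config$heads * config$d_k * config$d_model
    }
  }
  d_cls <- classifier_input_dim(config)
  n <- n + d_cls * config$classifier_hidden + config$classifier_hidden +
    config$classifier_hidden * 2 + 2
  as.integer(n)
}

# Generic parameter-tree utilities -------------------------------------------

#' @noRd
tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, function(x) tree_map(f, x)))
  f(tree)
}

#' @noRd
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

#' @noRd
tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

#' @noRd
tree_sum_sq <- function(tree) {
  if (is.list(tree)) return(sum(vapply(tree, tree_sum_sq, numeric(1))))
  sum(tree^2)
}
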