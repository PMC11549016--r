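# Training: Adam optimization of the cross-entropy loss, per-fold parameter
# resets, k-fold cross-validation, and the ablation harness.

#' @noRd
adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  new_params <- tree_map2(`-`, params, upd)
  class(new_params) <- "network_params"
  list(params = new_params, state = state)
}

#' @noRd
ce_loss <- function(prob, y) {
  -mean(log(pmax(prob[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Train the network on one fold
#'
#' Initializes fresh parameters from `seed` (parameters are reset for every
#' fold), minimizes the cross-entropy with Adam at the configured rate, and
#' returns final-epoch validation metrics. With an `fgm` configuration in
#' `"adversarial-train"` mode, each batch adds a second loss term computed on
#' the sign-gradient-perturbed inputs.
#'
#' @param train,val disjoint labelled record data frames, each containing
#'   both classes.
#' @param config a [network_config()].
#' @param tconfig a [train_config()].
#' @param fgm optional [fgm_config()] (adversarial training).
#' @param seed integer seed for this fold's initialization and batch order.
#' @param verbose emit a structured log line per epoch.
#' @return A list with `checkpoint` (params, config, tconfig, seed, history),
#'   `metrics` (one-row data frame on `val`) and `history` (per-epoch mean
#'   training loss).
#' @export
train_fold <- function(train, val, config, tconfig, fgm = NULL, seed = 1L,
                       verbose = FALSE) {
  if (nrow(train) == 0 || nrow(val) == 0) stop("empty train or validation split")
  if (length(intersect(train$id, val$id)) > 0) stop("train and val overlap")
  if (anyNA(train$label) || anyNA(val$label)) stop("labels required")
  if (length(unique(train$label)) < 2 || length(unique(val$label)) < 2) {
    stop("both classes required in train and validation sets")
  }

  codes <- if (config$use_path1) encode_records(train, "integer") else NULL
  pfeat <- if (config$use_path2) {
    encode_records(train, "pseknc", k = config$kmer_k)
  } else NULL
  pseknc_dim <- if (is.null(pfeat)) 4^config$kmer_k + 2L else ncol(pfeat)

  # standardize the path-2 features on training statistics so both path
  # summaries reach the classifier on comparable scales
  feat_center <- NULL; feat_scale <- NULL
  if (!is.null(pfeat) && tconfig$standardize) {
    feat_center <- colMeans(pfeat)
    feat_scale <- pmax(apply(pfeat, 2, stats::sd), 1e-8)
    pfeat <- scale_features(pfeat, feat_center, feat_scale)
  }

  params <- init_network_params(config, pseknc_dim, seed = seed)
  state <- adam_init(params)
  n <- nrow(train)
  y_all <- train$label
  adv <- !is.null(fgm) && fgm$mode == "adversarial-train" && fgm$epsilon > 0

  history <- numeric(tconfig$epochs)
  for (epoch in seq_len(tconfig$epochs)) {
    perm <- sample(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = tconfig$batch_size)) {
      idx <- perm[start:min(start + tconfig$batch_size - 1L, n)]
      cb <- if (is.null(codes)) NULL else codes[idx, , drop = FALSE]
      pb <- if (is.null(pfeat)) NULL else pfeat[idx, , drop = FALSE]
      y <- y_all[idx]
      Y <- cbind(1 - y, y)

      fw <- forward_batch(cb, pb, params, config, training = TRUE)
      losses <- c(losses, ce_loss(fw$prob, y))
      dlogits <- (fw$prob - Y) / length(idx)
      bw <- backward_batch(dlogits, fw, params, config)
      grads <- bw$grads

      if (adv) {
        p1o <- NULL; p2o <- NULL
        if (config$use_path1) {
          p1o <- fw$cache$p1$X
          if (fgm$target %in% c("both", "path1-embedding")) {
            p1o <- mapply(function(x, gx) x + fgm_perturb(gx, fgm$epsilon),
                          p1o, bw$d_p1X, SIMPLIFY = FALSE)
          }
        }
        if (config$use_path2) {
          p2o <- pb
          if (fgm$target %in% c("both", "path2-features")) {
            p2o <- pb + fgm_perturb(bw$d_pfeat, fgm$epsilon)
          }
        }
        fw2 <- forward_batch(cb, pb, params, config, training = TRUE,
                             p1_override = p1o, p2_override = p2o)
        bw2 <- backward_batch((fw2$prob - Y) / length(idx), fw2, params, config)
        grads <- tree_map2(`+`, grads, bw2$grads)
      }

      st <- adam_step(params, grads, state, tconfig$learning_rate)
      params <- st$params
      state <- st$state
    }
    history[epoch] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch=%d loss=%.6f", epoch, history[epoch]))
    }
  }

  checkpoint <- list(params = params, config = config, tconfig = tconfig,
                     seed = seed, history = history,
                     feat_center = feat_center, feat_scale = feat_scale)
  scores <- predict_proba(checkpoint, val)
  metrics <- evaluate_scores(scores, val$label)
  list(checkpoint = checkpoint, metrics = metrics, history = history)
}

#' k-fold cross-validation
#'
#' Partitions `records` with [make_folds()] (stratified), trains one model
#' per fold with parameters re-initialized from `tconfig$seed + fold`, and
#' reports per-fold and aggregate (mean, sd) metrics.
#'
#' @param records labelled record `data.frame`.
#' @param k number of folds.
#' @param config a [network_config()].
#' @param tconfig a [train_config()].
#' @param fgm optional [fgm_config()] for adversarial training.
#' @param keep_checkpoints retain per-fold checkpoints in the result.
#' @param verbose log per-epoch loss.
#' @return A list with `folds` (k-row metric data frame with a `fold`
#'   column), `summary` (mean and sd rows), and optionally `checkpoints`.
#' @export
cross_validate <- function(records, k = 10L, config = network_config(),
                           tconfig = train_config(), fgm = NULL,
                           keep_checkpoints = FALSE, verbose = FALSE) {
  folds <- make_folds(records, k = k, seed = tconfig$seed)
  rows <- vector("list", k)
  cks <- if (keep_checkpoints) vector("list", k) else NULL
  for (f in seq_len(k)) {
    val <- records[records$id %in% folds[[f]], , drop = FALSE]
    train <- records[!records$id %in% folds[[f]], , drop = FALSE]
    res <- train_fold(train, val, config, tconfig, fgm = fgm,
                      seed = tconfig$seed + f, verbose = verbose)
    rows[[f]] <- cbind(data.frame(fold = f), res$metrics)
    if (keep_checkpoints) cks[[f]] <- res$checkpoint
  }
  folds_df <- do.call(rbind, rows)
  met <- folds_df[, c("SEN", "SPE", "ACC", "MCC", "AUROC")]
  summary <- data.frame(stat = c("mean", "sd"),
                        rbind(colMeans(met), apply(met, 2, stats::sd)))
  out <- list(folds = folds_df, summary = summary)
  if (keep_checkpoints) out$checkpoints <- cks
  out
}

# Ablation harness ----------------------------------------------------------------

ABLATION_CELLS <- c("onehot", "integer", "pseknc", "combined",
                    "no-pe", "no-attention", "path1-only", "path2-only")

#' @noRd
ablation_config <- function(cell, base) {
  cfg <- unclass(base)
  switch(cell,
    "onehot" = { cfg$use_path2 <- FALSE; cfg$path1_scheme <- "onehot" },
    "integer" = ,
    "path1-only" = { cfg$use_path2 <- FALSE; cfg$path1_scheme <- "integer" },
    "pseknc" = ,
    "path2-only" = { cfg$use_path1 <- FALSE },
    "combined" = { },
    "no-pe" = { cfg$use_pe <- FALSE },
    "no-attention" = { cfg$use_attention <- FALSE },
    stop("unknown ablation cell: ", cell)
  )
  class(cfg) <- "network_config"
  cfg
}

#' Run the ablation grid
#'
#' One cross-validation per grid cell, varying the input features (one-hot /
#' integer / PseKNC / combined), the positional encoding, the attention
#' layers, or the active path, while everything else is held fixed. The
#' single-feature cells are single-path models by construction: `"integer"`
#' is the recurrent path alone (alias `"path1-only"`) and `"pseknc"` the
#' convolutional path alone (alias `"path2-only"`).
#'
#' @param records labelled record `data.frame`.
#' @param grid character vector of cell names (defaults to the six unique
#'   cells of the full grid).
#' @param k folds per cell.
#' @param config base [network_config()].
#' @param tconfig a [train_config()].
#' @param keep_checkpoints retain the per-fold checkpoints of each cell.
#' @return A list with `table` (one row per cell: mean metrics) and `runs`
#'   (the full cross-validation result per cell).
#' @export
run_ablation <- function(records, grid = c("onehot", "integer", "pseknc",
                                           "combined", "no-pe",
                                           "no-attention"),
                         k = 10L, config = network_config(),
                         tconfig = train_config(), keep_checkpoints = FALSE) {
  stopifnot(all(grid %in% ABLATION_CELLS))
  runs <- vector("list", length(grid))
  names(runs) <- grid
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- ablation_config(grid[i], config)
    cv <- cross_validate(records, k = k, config = cfg, tconfig = tconfig,
                         keep_checkpoints = keep_checkpoints)
    runs[[i]] <- cv
    mean_row <- cv$summary[cv$summary$stat == "mean",
                           c("SEN", "SPE", "ACC", "MCC", "AUROC")]
    rows[[i]] <- cbind(data.frame(cell = grid[i]), mean_row)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, runs = runs)
}

#' Write a metric table as TSV
#'
#' @param table a metric `data.frame` (e.g. `cross_validate(...)$folds` or
#'   `run_ablation(...)$table`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
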