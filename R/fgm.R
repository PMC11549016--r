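# Fast gradient method: sign-gradient perturbation of model inputs to probe
# (or harden) robustness against sequencing-error-like noise.

#' Fast-gradient-method perturbation
#'
#' delta = epsilon * sign(gradient), with sign(0) = 0; the adversarial input
#' is x + delta. Every component of delta lies in {-epsilon, 0, +epsilon},
#' so the perturbation sits on the boundary of the max-norm ball wherever
#' the gradient is nonzero.
#'
#' @param gradient numeric array: the loss gradient w.r.t. the input.
#' @param epsilon perturbation magnitude (>= 0).
#' @return An array of the same shape as `gradient`.
#' @export
fgm_perturb <- function(gradient, epsilon) {
  if (!all(is.finite(gradient))) stop("non-finite gradient")
  stopifnot(epsilon >= 0)
  epsilon * sign(gradient)
}

#' Evaluate a trained model under an FGM attack
#'
#' Computes clean metrics on the test set, then rebuilds each example's
#' inputs as x + epsilon * sign(grad_x J) — where J is the cross-entropy at
#' the true label — and reports the attacked metrics side by side. Path 1 is
#' perturbed at the embedding output (integer codes are not differentiable);
#' path 2 at the PseKNC feature vector; `target` selects either or both.
#'
#' @param checkpoint a trained checkpoint (list with `params`, `config`).
#' @param records labelled test records.
#' @param fgm an [fgm_config()].
#' @param batch_size evaluation batch size.
#' @return A list with one-row metric data frames `clean` and `attacked`,
#'   plus the score vectors `clean_scores`, `attacked_scores`.
#' @export
attack_evaluate <- function(checkpoint, records, fgm, batch_size = 256L) {
  params <- checkpoint$params; config <- checkpoint$config
  n <- nrow(records)
  labels <- records$label
  if (anyNA(labels)) stop("attack_evaluate requires labelled records")
  codes <- if (config$use_path1) encode_records(records, "integer") else NULL
  pfeat <- if (config$use_path2) {
    apply_feat_scaling(checkpoint,
                       encode_records(records, "pseknc", k = config$kmer_k))
  } else NULL

  clean <- numeric(n); attacked <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    cb <- if (is.null(codes)) NULL else codes[idx, , drop = FALSE]
    pb <- if (is.null(pfeat)) NULL else pfeat[idx, , drop = FALSE]
    fw <- forward_batch(cb, pb, params, config, training = FALSE)
    clean[idx] <- fw$prob[, 2]

    y <- labels[idx]
    Y <- cbind(1 - y, y)
    dlogits <- (fw$prob - Y) / length(idx)
    bw <- backward_batch(dlogits, fw, params, config)

    p1o <- NULL; p2o <- NULL
    if (config$use_path1 && fgm$target %in% c("both", "path1-embedding")) {
      p1o <- mapply(function(x, gx) x + fgm_perturb(gx, fgm$epsilon),
                    fw$cache$p1$X, bw$d_p1X, SIMPLIFY = FALSE)
    } else if (config$use_path1) {
      p1o <- fw$cache$p1$X
    }
    if (config$use_path2 && fgm$target %in% c("both", "path2-features")) {
      p2o <- pb + fgm_perturb(bw$d_pfeat, fgm$epsilon)
    } else if (config$use_path2) {
      p2o <- pb
    }
    fa <- forward_batch(cb, pb, params, config, training = FALSE,
                        p1_override = p1o, p2_override = p2o)
    attacked[idx] <- fa$prob[, 2]
  }
  list(clean = evaluate_scores(clean, labels),
       attacked = evaluate_scores(attacked, labels),
       clean_scores = clean, attacked_scores = attacked)
}
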