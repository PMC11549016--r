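# Feature encoders: integer encoding, k-mer profiles, PseKNC, one-hot,
# sinusoidal positional encoding.

# Base order of the integer code book: A->0, U->1, C->2, G->3. This follows
# the encoding worked example (AGCUUAG -> 0 3 2 1 1 0 3) and the alphabet
# order {A, U, C, G} of the source dictionary.
INTEGER_CODE_ORDER <- c("A", "U", "C", "G")

#' Integer-encode an RNA sequence
#'
#' Maps each base to a discrete code (A=0, U=1, C=2, G=3) for
#' embedding-table lookup. `integer_decode` inverts the map.
#'
#' @param seq a single RNA sequence string over A/C/G/U.
#' @return Integer vector of codes in 0..3, one per base.
#' @examples
#' integer_encode("AGCUUAG")  # 0 3 2 1 1 0 3
#' @export
integer_encode <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- match(chars, INTEGER_CODE_ORDER) - 1L
  if (anyNA(codes)) stop("sequence contains residues outside {A,C,G,U}")
  codes
}

#' @rdname integer_encode
#' @param codes integer vector of codes in 0..3.
#' @export
integer_decode <- function(codes) {
  if (any(codes < 0 | codes > 3)) stop("codes must lie in 0..3")
  paste(INTEGER_CODE_ORDER[codes + 1L], collapse = "")
}

#' One-hot encode an RNA sequence
#'
#' Row i carries a single 1 in the column given by the integer code of base
#' i; columns are ordered A, U, C, G for consistency with [integer_encode()].
#'
#' @inheritParams integer_encode
#' @return An L x 4 binary matrix.
#' @export
one_hot_encode <- function(seq) {
  codes <- integer_encode(seq)
  m <- matrix(0, nrow = length(codes), ncol = 4,
              dimnames = list(NULL, INTEGER_CODE_ORDER))
  m[cbind(seq_along(codes), codes + 1L)] <- 1
  m
}

#' Overlapping k-mer occurrence profile
#'
#' Counts length-k substrings in a sliding window of step 1. In
#' `"full-lexicographic"` mode (the model-facing default) all 4^k k-mers are
#' enumerated alphabetically so the profile has fixed width; in
#' `"observed-order"` mode only k-mers present in the sequence are listed, by
#' first occurrence.
#'
#' @inheritParams integer_encode
#' @param k k-mer length (>= 1; sequence must be at least k long).
#' @param mode enumeration mode, see Details.
#' @return A list of class `kmer_profile` with fields `k`, `order`
#'   (character vector of k-mers) and `counts` (aligned integer counts,
#'   summing to L - k + 1 in full-lexicographic mode).
#' @examples
#' kmer_profile("AGCUUAG", k = 2, mode = "observed-order")
#' @export
kmer_profile <- function(seq, k = 2L,
                         mode = c("full-lexicographic", "observed-order")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k")
  kmers <- substring(seq, seq_len(L - k + 1L), k:L)
  if (mode == "observed-order") {
    order_ <- unique(kmers)
  } else {
    order_ <- sort(do.call(paste0, expand.grid(
      rep(list(sort(RNA_ALPHABET)), k), stringsAsFactors = FALSE
    )[, k:1, drop = FALSE]))
  }
  counts <- as.integer(vapply(order_, function(m) sum(kmers == m), numeric(1)))
  structure(list(k = as.integer(k), order = order_, counts = counts,
                 mode = mode),
            class = "kmer_profile")
}

#' Pseudo k-tuple nucleotide composition (PseKNC) feature vector
#'
#' Combines the k-mer occurrence vector P with per-k-mer weights W by
#' element-wise addition, then appends a correlation pair R = (mean,
#' population standard deviation) computed over the *distinct nonzero* count
#' values. The composite feature is F = (P + W) followed by R, so its length
#' is 4^k + 2 in full-lexicographic mode.
#'
#' @inheritParams kmer_profile
#' @param weights per-k-mer weight vector aligned to the enumeration order,
#'   or a scalar recycled to every k-mer (default 1).
#' @return A list of class `pseknc` with fields `body` (counts + weights),
#'   `corr` (named mean/sd pair), `F` (the composite vector), `order`, `k`,
#'   `mode`.
#' @examples
#' pseknc("AGCUUAG", k = 2, mode = "observed-order")$F
#' # 3 2 2 2 2 1.5 0.5
#' @export
pseknc <- function(seq, k = 2L, weights = 1,
                   mode = c("full-lexicographic", "observed-order")) {
  mode <- match.arg(mode)
  prof <- kmer_profile(seq, k = k, mode = mode)
  n <- length(prof$counts)
  if (length(weights) == 1L) weights <- rep(weights, n)
  if (length(weights) != n) {
    stop("weights must be scalar or match the k-mer enumeration length (", n, ")")
  }
  body <- prof$counts + weights
  vals <- unique(prof$counts[prof$counts > 0])
  m <- mean(vals)
  s <- sqrt(mean((vals - m)^2))
  structure(list(body = body, corr = c(mean = m, sd = s),
                 F = c(body, m, s), order = prof$order, k = prof$k,
                 mode = mode),
            class = "pseknc")
}

#' Sinusoidal positional encoding matrix
#'
#' The standard transformer scheme: for 0-based position `pos` and feature
#' pair index `x` in 0..d/2-1, column 2x holds sin(pos * a^(-2x/d)) and
#' column 2x+1 holds cos(pos * a^(-2x/d)). Row 1 of the returned matrix is
#' position 0, i.e. (0, 1, 0, 1, ...). Added to embedded sequences so
#' position information survives order-agnostic attention layers.
#'
#' @param L number of positions (rows).
#' @param d even encoding width (columns).
#' @param a positive integer frequency base (default 10000).
#' @return An L x d matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(L, d, a = 10000L) {
  if (d %% 2 != 0) stop("encoding width d must be even")
  stopifnot(L >= 1, a >= 2)
  pos <- 0:(L - 1)
  pe <- matrix(0, nrow = L, ncol = d)
  for (x in 0:(d / 2 - 1)) {
    freq <- a^(-2 * x / d)
    pe[, 2 * x + 1] <- sin(pos * freq)
    pe[, 2 * x + 2] <- cos(pos * freq)
  }
  pe
}

#' Encode a set of records as a feature matrix
#'
#' Convenience wrapper used by the training pipeline and the command-line
#' `encode` subcommand.
#'
#' @param records a record `data.frame`.
#' @param scheme one of `"integer"`, `"pseknc"`, `"onehot"`.
#' @param k PseKNC k-mer length.
#' @param mode PseKNC enumeration mode.
#' @return For `"integer"` an n x L integer matrix of codes; for `"pseknc"`
#'   an n x (4^k + 2) numeric matrix; for `"onehot"` an n x (4L) matrix of
#'   flattened one-hot rows.
#' @export
encode_records <- function(records, scheme = c("integer", "pseknc", "onehot"),
                           k = 2L, mode = "full-lexicographic") {
  scheme <- match.arg(scheme)
  out <- switch(scheme,
    integer = t(vapply(records$seq, integer_encode,
                       integer(nchar(records$seq[1])))),
    pseknc = t(vapply(records$seq,
                      function(s) pseknc(s, k = k, mode = mode)$F,
                      numeric(4^k + 2))),
    onehot = t(vapply(records$seq,
                      function(s) as.vector(t(one_hot_encode(s))),
                      numeric(4 * nchar(records$seq[1]))))
  )
  rownames(out) <- records$id
  out
}
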