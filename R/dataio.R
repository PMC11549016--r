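# Sequence records, FASTA/label I/O, synthetic benchmark generation,
# redundancy filtering and dataset partitioning.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Assemble a table of RNA records
#'
#' Records are the universal input unit of the package: an id, an RNA
#' sequence over A/C/G/U, and an optional 0/1 label (1 = ac4C-positive).
#'
#' @param id character vector of identifiers.
#' @param seq character vector of sequences (same length as `id`).
#' @param label optional integer vector of 0/1 labels (`NA` allowed).
#' @return A `data.frame` with columns `id`, `seq`, `label`.
#' @export
rna_records <- function(id, seq, label = NA_integer_) {
  stopifnot(length(id) == length(seq))
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    label = as.integer(label), stringsAsFactors = FALSE)
  validate_records(out)
  out
}

#' Validate a record table
#'
#' Checks the record invariants: non-empty sequences over the RNA alphabet
#' and, when a window length is declared, a fixed length with cytidine at the
#' central position (the candidate modification site).
#'
#' @param records a record `data.frame` (see [rna_records()]).
#' @param window optional odd window length all records must have.
#' @return `records`, invisibly.
#' @export
validate_records <- function(records, window = NULL) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (any(!nzchar(records$seq))) {
    stop("empty sequence in record(s): ",
         paste(records$id[!nzchar(records$seq)], collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(RNA_ALPHABET, collapse = ""), "]"), records$seq)
  if (any(bad)) {
    stop("residues outside {A,C,G,U} in record(s): ",
         paste(utils::head(records$id[bad], 5), collapse = ", "))
  }
  if (!is.null(window)) {
    if (window %% 2 == 0) stop("window length must be odd")
    if (any(nchar(records$seq) != window)) {
      stop("records not of declared window length ", window)
    }
    centre <- (window + 1) / 2
    cc <- substr(records$seq, centre, centre)
    if (any(cc != "C")) {
      stop("central base is not C in record(s): ",
           paste(utils::head(records$id[cc != "C"], 5), collapse = ", "))
    }
  }
  invisible(records)
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and the DNA alphabet is accepted: T is mapped to
#' U on input (public ac4C window sets are frequently distributed as DNA).
#' Any other residue outside A/C/G/U is an error naming the record.
#'
#' @param path path to a FASTA file.
#' @param label optional 0/1 label assigned to every record in the file.
#' @return A record `data.frame` (columns `id`, `seq`, `label`), in file order.
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("malformed FASTA: file is empty: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA at line ", nonblank[1], ": expected '>' header")
  }
  prev_header <- 0L
  for (i in nonblank) {
    if (startsWith(trimws(lines[i]), ">")) {
      if (prev_header > 0L) {
        body <- lines[(prev_header + 1L):(i - 1L)]
        if (prev_header == i - 1L || !any(nzchar(trimws(body)))) {
          stop("malformed FASTA at line ", prev_header, ": header with no sequence")
        }
      }
      prev_header <- i
    }
  }
  if (prev_header == length(lines) ||
      !any(nzchar(trimws(lines[(prev_header + 1L):length(lines)])))) {
    stop("malformed FASTA at line ", prev_header, ": header with no sequence")
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  ids <- names(set)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("residues outside {A,C,G,U,T} in record(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  data.frame(id = unname(ids), seq = unname(seqs), label = as.integer(label),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records a record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write a label table
#'
#' Tab-separated with header `id<TAB>label`; labels are 0/1.
#'
#' @param path file path.
#' @return `read_labels`: a `data.frame` with columns `id`, `label`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer"))
  if (!identical(names(tab)[1:2], c("id", "label"))) {
    stop("label table must have header 'id<TAB>label'")
  }
  tab
}

#' @rdname read_labels
#' @param records a record `data.frame` with labels.
#' @export
write_labels <- function(records, path) {
  utils::write.table(records[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach labels from a label table to records
#'
#' @param records a record `data.frame`.
#' @param labels a `data.frame` with columns `id`, `label`.
#' @return `records` with the `label` column filled by id match.
#' @export
attach_labels <- function(records, labels) {
  idx <- match(records$id, labels$id)
  if (anyNA(idx)) {
    stop("labels missing for record(s): ",
         paste(utils::head(records$id[is.na(idx)], 5), collapse = ", "))
  }
  records$label <- as.integer(labels$label[idx])
  records
}

#' Specification of a synthetic benchmark dataset
#'
#' The generator emulates the structure of curated ac4C window sets: fixed
#' odd-length windows with the candidate cytidine at the centre in *both*
#' classes, and a C-rich trinucleotide signal ("CXX") enriched in positives.
#' `motif_rate` is the probability that any eligible trinucleotide frame in a
#' positive sequence is converted to a planted CXX (its first base set to C,
#' the two following bases left as background draws). The default rate of 0.5
#' produces a clearly separable benchmark; set it to 0 for a no-signal null.
#'
#' @param n_pos,n_neg number of positive / negative records (>= 1).
#' @param length odd window length (default 201).
#' @param motif_rate per-frame planting probability in \[0, 1\].
#' @param background length-4 base probabilities for A, C, G, U (sums to 1).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos, n_neg, length = 201L, motif_rate = 0.5,
                           background = rep(0.25, 4), seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, motif_rate >= 0, motif_rate <= 1)
  if (length %% 2 == 0) stop("window length must be odd")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length = as.integer(length), motif_rate = motif_rate,
                 background = background, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic benchmark dataset
#'
#' @param spec a [synthetic_spec()].
#' @return A record `data.frame` with `n_pos` positives followed by `n_neg`
#'   negatives; every record has C at the central position.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$length
  centre <- (L + 1L) / 2L
  frames <- seq(1L, L - 2L, by = 3L)
  eligible <- frames[frames + 2L < centre | frames > centre]

  draw <- function(n, positive) {
    vapply(seq_len(n), function(i) {
      s <- sample(RNA_ALPHABET, L, replace = TRUE, prob = spec$background)
      s[centre] <- "C"
      if (positive && spec$motif_rate > 0) {
        plant <- eligible[stats::runif(length(eligible)) < spec$motif_rate]
        s[plant] <- "C"
      }
      paste(s, collapse = "")
    }, character(1))
  }

  pos <- draw(spec$n_pos, TRUE)
  neg <- draw(spec$n_neg, FALSE)
  data.frame(
    id = c(sprintf("pos_%05d", seq_len(spec$n_pos)),
           sprintf("neg_%05d", seq_len(spec$n_neg))),
    seq = c(pos, neg),
    label = c(rep(1L, spec$n_pos), rep(0L, spec$n_neg)),
    stringsAsFactors = FALSE
  )
}

#' Ungapped positional identity between two equal-length sequences
#' @noRd
seq_identity <- function(a, b) {
  mean(strsplit(a, "", fixed = TRUE)[[1]] == strsplit(b, "", fixed = TRUE)[[1]])
}

#' Greedy redundancy filter
#'
#' Scans records in input order and keeps a record iff its ungapped
#' positional identity to every already-kept record is below `threshold`.
#' This stands in for CD-HIT-style clustering at the same threshold on
#' equal-length windows.
#'
#' @param records a record `data.frame` of equal-length sequences.
#' @param threshold identity threshold in (0, 1]; the curated ac4C sets use 0.8.
#' @return The kept subset of `records`, input order preserved.
#' @export
redundancy_filter <- function(records, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(records)
  if (n == 0L) return(records)
  if (length(unique(nchar(records$seq))) != 1L) {
    stop("redundancy_filter requires equal-length sequences")
  }
  chars <- do.call(rbind, strsplit(records$seq, "", fixed = TRUE))
  keep <- logical(n)
  kept_rows <- integer(0)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in kept_rows) {
      if (mean(chars[i, ] == chars[j, ]) >= threshold) { ok <- FALSE; break }
    }
    if (ok) { keep[i] <- TRUE; kept_rows <- c(kept_rows, i) }
  }
  records[keep, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Randomly partitions records at the given ratio, stratified by label, so a
#' balanced input stays balanced in both parts (the curated ac4C benchmark
#' uses a 4:1 train:test ratio).
#'
#' @param records a labelled record `data.frame`.
#' @param ratio length-2 integer vector, train:test (default `c(4, 1)`).
#' @param balanced stratify by label (requires both classes present).
#' @param seed integer seed.
#' @return A list of class `dataset_split` with elements `train`, `test`,
#'   `ratio`, `seed`.
#' @export
split_dataset <- function(records, ratio = c(4, 1), balanced = TRUE, seed = 1L) {
  stopifnot(nrow(records) >= 2, length(ratio) == 2, all(ratio > 0))
  if (balanced) {
    if (anyNA(records$label)) stop("balanced split requires labels")
    if (length(unique(records$label)) < 2) {
      stop("balanced split requires both classes")
    }
    strata <- split(seq_len(nrow(records)), records$label)
  } else {
    strata <- list(seq_len(nrow(records)))
  }
  set.seed(seed)
  frac <- ratio[1] / sum(ratio)
  train_idx <- integer(0)
  for (s in strata) {
    s <- sample(s)
    n_train <- round(length(s) * frac)
    train_idx <- c(train_idx, s[seq_len(n_train)])
  }
  train_idx <- sort(train_idx)
  structure(list(train = records[train_idx, , drop = FALSE],
                 test = records[-train_idx, , drop = FALSE],
                 ratio = ratio, seed = as.integer(seed)),
            class = "dataset_split")
}

#' Stratified k-fold partition
#'
#' Shuffles ids within each class and deals them round-robin into `k` folds,
#' carrying the deal across classes so fold sizes differ by at most one both
#' overall and per class.
#'
#' @param records a labelled record `data.frame`.
#' @param k number of folds (>= 2; the evaluation protocol uses 10).
#' @param seed integer seed.
#' @return A list of `k` character vectors of ids (pairwise disjoint,
#'   jointly exhaustive).
#' @export
make_folds <- function(records, k = 10L, seed = 1L) {
  n <- nrow(records)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of records")
  set.seed(seed)
  strata <- if (anyNA(records$label)) list(seq_len(n)) else
    split(seq_len(n), records$label)
  order_all <- unlist(lapply(strata, sample), use.names = FALSE)
  fold_of <- rep_len(seq_len(k), n)
  ids <- records$id[order_all]
  lapply(seq_len(k), function(f) ids[fold_of == f])
}

#' Write a split or fold assignment as a TSV manifest
#'
#' @param assignment named list mapping subset name to a character vector of ids.
#' @param path output path; written as `id<TAB>subset` with header.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(assignment, path) {
  df <- do.call(rbind, lapply(names(assignment), function(nm) {
    data.frame(id = assignment[[nm]], subset = nm, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
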