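test_that("read_fasta normalizes case and alphabet and preserves order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "acguu", ">s2", "ACGT", ">s3", "GG", "CC"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("s1", "s2", "s3"))
  expect_equal(recs$seq, c("ACGUU", "ACGU", "GGCC"))
})

test_that("read_fasta names the offending line or record on bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGU", ">s1", "ACGU"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">s1", ">s2", "ACGU"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">ok", "ACGU", ">bad", "ACGN"), f)
  expect_error(read_fasta(f), "bad")
})

test_that("FASTA and label tables round-trip through files", {
  recs <- random_records(6, 12, seed = 3)
  f <- withr::local_tempfile(fileext = ".fa")
  l <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(recs, f)
  write_labels(recs, l)
  back <- attach_labels(read_fasta(f), read_labels(l))
  expect_equal(back$id, recs$id)
  expect_equal(back$seq, recs$seq)
  expect_equal(back$label, recs$label)
})

test_that("synthetic generation is seed-deterministic with balanced labels", {
  spec <- synthetic_spec(5, 5, length = 21, seed = 7)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a, b)
  expect_equal(sum(a$label == 1), 5)
  expect_equal(sum(a$label == 0), 5)
  expect_error(synthetic_spec(5, 5, length = 20), "odd")
})

test_that("every synthetic record carries the central cytidine", {
  recs <- generate_synthetic(synthetic_spec(30, 30, length = 21, seed = 2))
  expect_true(all(substr(recs$seq, 11, 11) == "C"))
  expect_silent(validate_records(recs, window = 21))
  long <- generate_synthetic(synthetic_spec(10, 10, length = 201, seed = 2))
  expect_true(all(substr(long$seq, 101, 101) == "C"))
})

test_that("motif planting enriches C-initial 2-mers in positives", {
  count_c2 <- function(recs) {
    mean(vapply(recs$seq[recs$label == 1], function(s) {
      prof <- kmer_profile(s, 2)
      sum(prof$counts[startsWith(prof$order, "C")])
    }, numeric(1)))
  }
  planted <- generate_synthetic(synthetic_spec(500, 1, length = 51,
                                               motif_rate = 0.5, seed = 5))
  flat <- generate_synthetic(synthetic_spec(500, 1, length = 51,
                                            motif_rate = 0, seed = 5))
  expect_gt(count_c2(planted), count_c2(flat))
})

test_that("redundancy filter matches the brute-force all-pairs oracle", {
  expect_equal(nrow(redundancy_filter(
    data.frame(id = c("a", "b"), seq = c("ACGUACGUAC", "ACGUACGUAC"),
               label = NA_integer_), 0.8)), 1)
  two <- data.frame(id = c("a", "b"),
                    seq = c("AAAAAAAAAA", "AAACCCCCCC"), label = NA_integer_)
  expect_equal(nrow(redundancy_filter(two, 0.8)), 2)

  recs <- random_records(10, 20, seed = 9)
  # inject near-duplicates to exercise the threshold
  recs$seq[4] <- recs$seq[1]
  recs$seq[7] <- paste0("A", substr(recs$seq[2], 2, 20))
  kept <- redundancy_filter(recs, 0.8)
  expect_equal(kept$seq, redundancy_oracle(recs$seq, 0.8))

  expect_identical(redundancy_filter(kept, 0.8), kept)  # idempotent
  expect_error(redundancy_filter(
    data.frame(id = 1:2, seq = c("ACG", "ACGU"), label = NA_integer_)),
    "equal-length")
})

test_that("stratified splitting hits the requested ratio deterministically", {
  recs <- random_records(100, 10, seed = 1)
  sp <- split_dataset(recs, c(4, 1), seed = 5)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  sp2 <- split_dataset(recs, c(4, 1), seed = 5)
  expect_identical(sp$train$id, sp2$train$id)

  one_class <- transform(recs, label = 1L)
  expect_error(split_dataset(one_class, balanced = TRUE), "both classes")
})

test_that("fold partition is exhaustive, disjoint, stratified, near-equal", {
  recs <- random_records(100, 10, seed = 2)
  folds <- make_folds(recs, k = 10, seed = 3)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 10))
  expect_setequal(unlist(folds), recs$id)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  }
  # per-fold class balance within 1
  for (f in folds) {
    labs <- recs$label[match(f, recs$id)]
    expect_lte(abs(sum(labs == 1) - sum(labs == 0)), 1)
  }

  odd <- random_records(103, 10, seed = 4)
  sizes <- lengths(make_folds(odd, k = 10, seed = 3))
  expect_true(all(sizes %in% c(10, 11)))
  expect_equal(sum(sizes), 103)

  expect_error(make_folds(recs, k = 101), "exceeds")
  expect_error(make_folds(recs, k = 1), ">= 2")
})
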