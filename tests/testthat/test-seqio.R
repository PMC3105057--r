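write_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_fasta parses records in order and uppercases", {
  f <- write_tmp(c(">a short peptide", "NTALT"))
  rec <- read_fasta(f)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$id, "a")
  expect_equal(rec$description, "short peptide")
  expect_equal(rec$sequence, "NTALT")
  expect_equal(nchar(rec$sequence), 5L)

  f2 <- write_tmp(c(">b", "acd", "efg", ">c", "MKV"))
  rec2 <- read_fasta(f2)
  expect_equal(rec2$id, c("b", "c"))
  expect_equal(rec2$sequence, c("ACDEFG", "MKV"))
})

test_that("read_fasta reports malformed input with line numbers", {
  expect_equal(nrow(read_fasta(write_tmp(character(0)))), 0L)
  expect_error(read_fasta(write_tmp(c("ACDE", ">a", "ACDE"))), "line 1")
  expect_error(read_fasta(write_tmp(c(">a", "ACDE", ">", "MKV"))), "line 3")
  expect_error(read_fasta(write_tmp(c(">a", "ACDE", ">b"))), "empty sequence")
  expect_error(read_fasta(write_tmp(c(">a", "AC", ">a", "MK"))), "duplicate")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("fasta round-trip is byte-identical for canonical input", {
  set.seed(3)
  recs <- data.frame(id = c("p1", "p2", "p3"),
                     description = c("", "desc here", ""),
                     sequence = vapply(c(10, 75, 130), random_protein,
                                       character(1)),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_identical(back$sequence, recs$sequence)
  expect_identical(back$id, recs$id)
})

test_that("canonicalize implements the three policies", {
  expect_equal(canonicalize("ACXDE", "drop"), "ACDE")
  expect_equal(canonicalize("ACDE", "strict"), "ACDE")
  expect_equal(canonicalize("ABZ", "map_to_most_frequent"), "ANQ")
  expect_equal(canonicalize("AUX-", "map_to_most_frequent"), "AC")
  expect_equal(canonicalize("ac-de", "drop"), "ACDE")
  err <- tryCatch(canonicalize("AXB", "strict"), error = identity)
  expect_match(conditionMessage(err), "X@2")
  expect_match(conditionMessage(err), "B@3")
  # canonicalization catches the invalid alphabet of a parsed record
  expect_error(canonicalize("WXYZ-ILLEGAL", "strict"), "strict")
})

make_labeled <- function(n_pos, n_neg, subsets = NULL) {
  ids <- c(sprintf("p%d", seq_len(n_pos)), sprintf("n%d", seq_len(n_neg)))
  d <- data.frame(id = ids,
                  sequence = vapply(rep(30, n_pos + n_neg), random_protein,
                                    character(1)),
                  label = rep(c("AFP", "NONAFP"), c(n_pos, n_neg)),
                  stringsAsFactors = FALSE)
  if (!is.null(subsets)) d$subset <- c(subsets, rep(NA, n_neg))
  d
}

test_that("assign_folds places positives by subset and deals negatives", {
  set.seed(5)
  d <- make_labeled(7, 14, subsets = 1:7)
  out <- assign_folds(d, n_folds = 7, seed = 9)
  expect_true(all(table(out$fold) == 3))
  pos <- out[out$label == "AFP", ]
  expect_equal(pos$fold, pos$subset)
  # negatives balanced to within one
  negs <- table(out$fold[out$label == "NONAFP"])
  expect_lte(max(negs) - min(negs), 1)
  # determinism
  out2 <- assign_folds(d, n_folds = 7, seed = 9)
  expect_identical(out$fold, out2$fold)
  out3 <- assign_folds(d, n_folds = 7, seed = 10)
  expect_false(identical(out$fold, out3$fold))
})

test_that("reference subset declaration yields the published fold sizes", {
  set.seed(5)
  subsets <- afp_reference_subsets()
  d <- data.frame(id = c(subsets$id, sprintf("neg%d", 1:70)),
                  sequence = "", stringsAsFactors = FALSE)
  d$label <- rep(c("AFP", "NONAFP"), c(nrow(subsets), 70))
  out <- assign_folds(d, stats::setNames(subsets$subset, subsets$id),
                      n_folds = 7, seed = 1)
  pos_sizes <- as.integer(table(out$fold[out$label == "AFP"]))
  expect_equal(pos_sizes, c(1, 33, 1, 3, 3, 1, 2))
})

test_that("assign_folds validates its inputs", {
  d <- make_labeled(2, 4, subsets = c(1, 2))
  expect_error(assign_folds(d, positive_subsets = c(p1 = 1L), n_folds = 3,
                            seed = 1),
               "missing from positive_subsets")
  expect_error(assign_folds(d, positive_subsets = c(p1 = 1L, p2 = 9L),
                            n_folds = 3, seed = 1), "1\\.\\.3")
})

test_that("label tables round-trip and reject unknown labels", {
  f <- withr::local_tempfile()
  writeLines(c("a\tAFP\t2", "b\tNONAFP\t"), f)
  lab <- read_labels(f)
  expect_equal(lab$label, c("AFP", "NONAFP"))
  expect_equal(lab$subset, c(2L, NA_integer_))
  writeLines(c("a\tYES"), f)
  expect_error(read_labels(f), "AFP")

  recs <- data.frame(id = c("a", "b"), sequence = c("MK", "MV"),
                     stringsAsFactors = FALSE)
  writeLines(c("a\tAFP\t2", "b\tNONAFP\t"), f)
  merged <- label_dataset(recs, read_labels(f))
  expect_equal(merged$label, c("AFP", "NONAFP"))
  expect_error(label_dataset(data.frame(id = "zz", sequence = "MK"),
                             read_labels(f)), "unlabeled")
})
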