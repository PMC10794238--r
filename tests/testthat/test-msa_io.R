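test_that("aligned FASTA is parsed with domain ranges and normalization", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFGHIKL", ">b", "ACDEFGHIK-", ">c", "acdefghikX"),
             f)
  aln <- suppressMessages(
    read_paired_alignment(f, list(DHp = c(0, 4), Rec = c(4, 10))))
  expect_s3_class(aln, "paired_alignment")
  expect_equal(aln$column_count, 10L)
  expect_equal(nrow(aln$seqs), 3L)
  # lower case upper-cased, X mapped to gap and counted
  expect_equal(aln$seqs[3, 10], "-")
  expect_equal(aln$ambiguous_count, 1L)
  expect_equal(domain_columns(aln, "Rec"), 5:10)
})

test_that("ragged, empty and mis-ranged inputs raise the right errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFGHIKL", ">b", "ACDEFGHIK"), f)
  expect_error(read_paired_alignment(f, list(all = c(0, 10))), "ragged")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f2)
  expect_error(read_paired_alignment(f2, list(all = c(0, 10))),
               "input error|empty")
  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFGHIKL"), f3)
  expect_error(read_paired_alignment(f3, list(A = c(0, 6), B = c(5, 10))),
               "overlap")
  expect_error(read_paired_alignment(f3, list(A = c(0, 20))),
               "out of bounds")
})

test_that("sequence filter precedes column filter and indices are recorded", {
  # one sequence with 30% gaps is dropped at (0.2, 0.5); afterwards one
  # column has 3/4 gaps and is dropped
  strs <- c("A-CDEFGHIK",
            "A-CDEFGHIK",
            "A-CDEFGHIK",
            "AACDEFGHIK",
            "A---CDEF--")   # 5/10 gaps -> dropped? 0.5 > 0.2 yes
  aln <- aln_from_strings(strs, list(DHp = c(0, 5), Rec = c(5, 10)))
  filt <- filter_alignment(aln)
  expect_equal(nrow(filt$seqs), 4L)
  expect_equal(filt$removed_columns, 1L)   # 0-based index of column 2
  expect_equal(filt$column_count, 9L)
  expect_equal(filt$domain_ranges$DHp, c(0L, 4L))
  expect_equal(filt$domain_ranges$Rec, c(4L, 9L))
})

test_that("column gap fractions are recomputed after sequence removal", {
  # brute-force oracle: recompute both filters naively on the raw matrix
  set.seed(42)
  n <- 40L; L <- 25L
  m <- matrix(sample(c(AA, "-"), n * L, replace = TRUE,
                     prob = c(rep(0.045, 20), 0.1)), n, L)
  # make 3 sequences gappy and 2 columns gappy-after-removal
  m[1:3, ] <- "-"
  m[1:3, 1:12] <- "A"
  aln <- paired_alignment(m, paste0("s", 1:n), list(all = c(0L, L)))
  filt <- filter_alignment(aln, 0.2, 0.5)

  keep_seq <- rowMeans(m == "-") <= 0.2
  col_frac <- colMeans(m[keep_seq, , drop = FALSE] == "-")
  keep_col <- col_frac <= 0.5
  expect_equal(nrow(filt$seqs), sum(keep_seq))
  expect_equal(filt$removed_columns, which(!keep_col) - 1L)
  expect_identical(filt$seqs, m[keep_seq, keep_col, drop = FALSE])
})

test_that("filtering is idempotent and FASTA round-trips", {
  set.seed(7)
  m <- matrix(sample(c(AA, "-"), 30 * 12, replace = TRUE,
                     prob = c(rep(0.0475, 20), 0.05)), 30, 12)
  aln <- paired_alignment(m, paste0("s", 1:30),
                          list(DHp = c(0L, 5L), Rec = c(5L, 12L)))
  f1 <- filter_alignment(aln)
  f2 <- filter_alignment(f1)
  expect_identical(f1$seqs, f2$seqs)
  expect_identical(f1$removed_columns, f2$removed_columns)

  f <- withr::local_tempfile(fileext = ".fasta")
  write_paired_alignment(f1, f)
  back <- read_paired_alignment(f, f1$domain_ranges)
  expect_identical(back$seqs, f1$seqs)
  expect_identical(back$ids, f1$ids)
})

test_that("frequencies exclude gaps and match naive counting", {
  aln <- aln_from_strings(c("AAC", "AAC", "-AC", "VAC"))
  fm <- estimate_frequencies(aln, uniform_bg, pseudocount = 0)
  expect_equal(unname(fm$f_single[1, "A"]), 2 / 3)
  expect_equal(unname(fm$f_single[1, "V"]), 1 / 3)
  expect_equal(as.integer(fm$effective_counts), c(3L, 4L, 4L))
  expect_equal(rowSums(fm$f_single), rep(1, 3))

  # pairwise table equals a naive double loop over non-gapped rows
  set.seed(11)
  m <- matrix(sample(c(AA[1:4], "-"), 60 * 5, replace = TRUE), 60, 5)
  aln2 <- paired_alignment(m, paste0("s", 1:60), list(all = c(0L, 5L)))
  fm2 <- estimate_frequencies(aln2, uniform_bg, pseudocount = 0)
  for (pr in list(c(1, 2), c(2, 5))) {
    i <- pr[1]; j <- pr[2]
    naive <- matrix(0, 20, 20, dimnames = list(AA, AA))
    nobs <- 0
    for (r in 1:60) {
      a <- m[r, i]; b <- m[r, j]
      if (a != "-" && b != "-") {
        naive[a, b] <- naive[a, b] + 1
        nobs <- nobs + 1
      }
    }
    expect_equal(pair_frequencies(fm2, i, j), naive / nobs)
  }
})

test_that("pair marginals reproduce gap-consistent single frequencies", {
  set.seed(3)
  m <- matrix(sample(c(AA, "-"), 80 * 6, replace = TRUE,
                     prob = c(rep(0.0475, 20), 0.05)), 80, 6)
  aln <- paired_alignment(m, paste0("s", 1:80), list(all = c(0L, 6L)))
  fm <- estimate_frequencies(aln, uniform_bg, pseudocount = 0)
  fij <- pair_frequencies(fm, 2, 4)
  both <- m[, 2] != "-" & m[, 4] != "-"
  fi_sub <- tabulate(match(m[both, 2], AA), 20) / sum(both)
  expect_equal(unname(rowSums(fij)), fi_sub, tolerance = 1e-6)
})

test_that("degenerate and invalid inputs are rejected", {
  aln <- aln_from_strings(c("A-", "A-"))
  expect_error(estimate_frequencies(aln, uniform_bg, 0),
               "degenerate-column")
  bad_bg <- uniform_bg; bad_bg["C"] <- 0
  aln2 <- aln_from_strings(c("AC", "CA"))
  expect_error(estimate_frequencies(aln2, bad_bg), "strictly positive")
  expect_error(filter_alignment(aln_from_strings(c("----", "----"))),
               "empty-alignment")
})
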