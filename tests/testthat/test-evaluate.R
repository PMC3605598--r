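sam_line <- function(qname, flag, rname, pos, cigar, seq) {
  paste(qname, flag, rname, pos, 60L, cigar, "*", 0L, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

write_sam <- function(lines, path) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:chr1\tLN:100000", lines), path)
  path
}

test_that("truth_from_sam groups by reference, start and prefix", {
  seq1 <- strrep("ACGTACGTACGTACGT", 4)   # 64 bases
  seq2 <- paste0("TTTT", substr(seq1, 5, 64))
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(c(
    sam_line("dupA1", 0, "chr1", 100, "64M", seq1),
    sam_line("dupA2", 0, "chr1", 100, "4S60M", seq1),
    sam_line("lone1", 0, "chr1", 101, "64M", seq1),   # start differs
    sam_line("lone2", 0, "chr1", 100, "64M", seq2),   # prefix differs
    sam_line("masked", 0, "chr1", 100, "5H59M", seq1),# hard-clipped start
    sam_line("unmapped", 4, "chr1", 0, "*", seq1)
  ), path)
  expect_message(ts <- truth_from_sam(path), "soft-clipped")
  expect_identical(ts$source, "alignment-derived")
  sizes <- sort(lengths(ts$clusters))
  expect_identical(unname(sizes), c(1L, 1L, 2L))
  pair <- ts$clusters[[which(lengths(ts$clusters) == 2)]]
  expect_setequal(pair, c("dupA1", "dupA2"))
})

test_that("reverse-strand records are canonicalized to a strand-aware start", {
  # two duplicates sequenced from the minus strand: SAM shows the reverse
  # complement, aligned so that both alignments END at the duplicates'
  # shared start on the forward axis
  seq_long <- strrep("AACGTGCTGA", 6)            # 60 bases, ends at 159
  seq_short <- substr(seq_long, 11, 60)          # 50 bases, ends at 159
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(c(
    sam_line("rev1", 16, "chr1", 100, "60M", seq_long),
    sam_line("rev2", 16, "chr1", 110, "50M", seq_short),
    sam_line("fwd_same_pos", 0, "chr1", 159, "50M", seq_short)
  ), path)
  ts <- truth_from_sam(path)
  expect_length(ts$clusters, 2L)
  pair <- ts$clusters[[which(lengths(ts$clusters) == 2)]]
  expect_setequal(pair, c("rev1", "rev2"))
  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "r1\t0\tchr1"), bad)
  expect_error(truth_from_sam(bad), "line 2")
})

test_that("duplicate_rate follows the one-representative-per-cluster rule", {
  singles <- truth_set(as.list(letters[1:10]))
  expect_identical(duplicate_rate(singles, 10L), 0)
  cs <- truth_set(c(lapply(1:60, function(i) sprintf("s%d", i)),
                    lapply(1:20, function(i) sprintf("p%da", i))))
  cs$clusters[61:80] <- lapply(1:20, function(i) sprintf("p%d%s", i,
                                                         c("a", "b")))
  expect_identical(duplicate_rate(cs, 100L), 20)
  expect_error(duplicate_rate(singles, 0L), "positive")
  expect_error(duplicate_rate(singles, 12L), "partition covers")
})

test_that("jaccard reproduces the enumerated worked example", {
  truth <- truth_set(list(c("A", "B", "C"), "D"))
  pred <- truth_set(list(c("A", "B"), c("C", "D")))
  pc <- pair_counts(truth, pred)
  expect_identical(pc, c(a = 1, b = 2, c = 1))
  expect_identical(pc, oracle_pair_counts(truth, pred))
  expect_equal(jaccard(truth, pred), 0.25)
})

test_that("jaccard limits: identity, all-singleton prediction, no pairs", {
  truth <- truth_set(list(c("A", "B"), c("C", "D", "E"), "F"))
  expect_identical(jaccard(truth, truth), 1)
  singles <- truth_set(as.list(c("A", "B", "C", "D", "E", "F")))
  expect_identical(jaccard(truth, singles), 0)
  expect_identical(jaccard(singles, singles), 1)
  other <- truth_set(as.list(c("A", "B", "X")))
  expect_error(jaccard(truth, other), "different reads")
})

test_that("pair-count identities hold on random partitions", {
  set.seed(171)
  for (trial in 1:20) {
    n <- sample(20:200, 1)
    ids <- sprintf("r%03d", seq_len(n))
    truth <- truth_set(unname(split(ids, sample(ceiling(n / 3), n,
                                                replace = TRUE))))
    pred <- truth_set(unname(split(ids, sample(ceiling(n / 2), n,
                                               replace = TRUE))))
    pc <- pair_counts(truth, pred)
    within_t <- sum(choose(lengths(truth$clusters), 2))
    within_p <- sum(choose(lengths(pred$clusters), 2))
    expect_identical(unname(pc["a"] + pc["b"]), within_t)
    expect_identical(unname(pc["a"] + pc["c"]), within_p)
    # swapping the roles swaps b and c
    rev_pc <- pair_counts(pred, truth)
    expect_identical(unname(rev_pc[c("a", "b", "c")]),
                     unname(pc[c("a", "c", "b")]))
    if (n <= 60)
      expect_identical(pc, oracle_pair_counts(truth, pred))
  }
})

test_that("threshold_sweep tabulates rate and jaccard per threshold", {
  sim <- sim_bin(50, seed = 181)
  tab <- threshold_sweep(sim$flowgrams, c(0, 0.05), truth = sim$truth)
  expect_identical(names(tab),
                   c("threshold", "duplicate_rate", "jaccard", "n_clusters"))
  expect_identical(tab$duplicate_rate[1], 0)
  expect_identical(tab$jaccard[1], 0)
  expect_true(all(diff(tab$duplicate_rate) >= 0))
  expect_gt(tab$jaccard[2], 0.8)
})
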