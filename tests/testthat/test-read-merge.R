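# Read-pair merging: overlap detection, quality recombination, round trips.

mk_read <- function(id, seq, q = 30) {
  list(id = id, seq = seq, qual = rep(q, nchar(seq)))
}

test_that("exact suffix-prefix overlaps are found at the true length", {
  r1 <- "GGGGACGTACGT"
  r2rc <- "ACGTACGTTTTT"
  expect_equal(find_best_overlap(r1, r2rc, min_overlap = 5), 8L)
  # no shared window within tolerance
  expect_true(is.na(find_best_overlap("AAAAAAAAAA", "CCCCCCCCCC",
                                      min_overlap = 4)))
  expect_error(find_best_overlap("", "ACGT"), "empty")
})

test_that("N bases are mismatch-neutral in the overlap search", {
  r1 <- "GGGGACGTACGT"
  r2rc <- sub("ACGTACGT", "ACGTNCGT", "ACGTACGTTTTT")
  expect_equal(find_best_overlap(r1, r2rc, min_overlap = 6,
                                 max_mismatch_frac = 0), 8L)
})

test_that("quality recombination follows the agree/disagree rules", {
  # 150-nt fragment, two 100-nt reads, overlap 50
  set.seed(2)
  frag <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  r1 <- mk_read("p", substr(frag, 1, 100), q = 30)
  r2 <- mk_read("p", toxdiverge:::revcomp(substr(frag, 51, 150)), q = 35)
  cr <- merge_pair(r1, r2)
  expect_s3_class(cr, "composite_read")
  expect_equal(cr$seq, frag)
  expect_equal(cr$overlap, 50L)
  expect_equal(nchar(cr$seq), 100 + 100 - cr$overlap)
  expect_equal(cr$qual, c(rep(30, 50), rep(pmin(30 + 35, 93), 50), rep(35, 50)))
  # disagreement: higher-quality base, quality |q1 - q2|
  r1d <- mk_read("d", substr(frag, 1, 100), q = 40)
  s2 <- substr(frag, 51, 150)
  mism <- s2
  substr(mism, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(s2, 1, 1))[1]
  r2d <- mk_read("d", toxdiverge:::revcomp(mism), q = 20)
  crd <- merge_pair(r1d, r2d)
  expect_equal(substr(crd$seq, 51, 51), substr(frag, 51, 51))  # r1 base wins
  expect_equal(crd$qual[51], 20)
  # quality tie: base from r1 with quality 2
  r2t <- mk_read("t", toxdiverge:::revcomp(mism), q = 40)
  crt <- merge_pair(r1d, r2t)
  expect_equal(substr(crt$seq, 51, 51), substr(frag, 51, 51))
  expect_equal(crt$qual[51], 2)
})

test_that("malformed records and unmergeable pairs are reported", {
  bad <- list(id = "bad", seq = "ACGT", qual = c(30, 30))
  expect_error(merge_pair(bad, mk_read("x", "ACGTACGTACGT")), "malformed")
  pairs <- tibble::tibble(
    id = "nope",
    seq1 = paste(rep("A", 40), collapse = ""),
    qual1 = list(rep(30, 40)),
    seq2 = paste(rep("C", 40), collapse = ""),  # revcomp = G...G, no overlap
    qual2 = list(rep(30, 40)))
  res <- merge_read_pairs(pairs)
  expect_equal(nrow(res$merged), 0)
  expect_equal(res$rejected$id, "nope")
  expect_equal(res$summary$n_rejected, 1)
})

test_that("merging the swapped pair yields the reverse-complement composite", {
  set.seed(3)
  frag <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  r1 <- mk_read("p", substr(frag, 1, 100), q = 30)
  r2 <- mk_read("p", toxdiverge:::revcomp(substr(frag, 51, 150)), q = 33)
  ab <- merge_pair(r1, r2)
  ba <- merge_pair(r2, r1)
  expect_equal(ba$seq, toxdiverge:::revcomp(ab$seq))
  expect_equal(ba$qual, rev(ab$qual))
})

test_that("error-free simulated pairs reconstruct their source fragments", {
  cfg <- sim_config(n_read_pairs = 400, error_rate = 0, seed = 4)
  set.seed(4)
  tr <- c(T1 = toxdiverge:::random_nt(500), T2 = toxdiverge:::random_nt(400))
  rd <- simulate_reads(tr, c(0.6, 0.4), cfg)
  res <- merge_read_pairs(rd)
  expect_equal(nrow(res$merged), 400)
  expect_equal(res$summary$mean_length, cfg$fragment_length)
  frag <- substr(tr[rd$transcript], rd$start, rd$start + cfg$fragment_length - 1)
  expect_identical(res$merged$seq, unname(frag))
  # composites are substrings of their source transcripts
  expect_true(all(mapply(grepl, res$merged$seq, tr[rd$transcript], fixed = TRUE)))
})

test_that("true overlap length is recovered under realistic error rates", {
  cfg <- sim_config(n_read_pairs = 2000, error_rate = 0.005, seed = 6)
  set.seed(6)
  tr <- c(T1 = toxdiverge:::random_nt(600))
  rd <- simulate_reads(tr, 1, cfg)
  res <- merge_read_pairs(rd, min_overlap = 10, max_mismatch_frac = 0.1)
  true_ov <- 2 * cfg$read_length - cfg$fragment_length
  ok <- res$merged$overlap == true_ov
  expect_gte(sum(ok) / nrow(rd), 0.99)
})

test_that("adapter suffixes are trimmed by exact match before merging", {
  adapter <- "AGATCGGAAGAGC"
  core <- "ACGTACGTACGTACGTACGTACGT"
  r <- toxdiverge:::trim_adapter(paste0(core, adapter), rep(30, 24 + 13), adapter)
  expect_equal(r$seq, core)
  expect_equal(length(r$qual), nchar(core))
})

test_that("FASTQ io round-trips reads and qualities", {
  tb <- tibble::tibble(id = c("r1", "r2"),
                       seq = c("ACGTN", "GGGCC"),
                       qual = list(c(40, 40, 2, 10, 0), rep(35, 5)))
  path <- tempfile(fileext = ".fastq")
  write_fastq_tbl(tb, path)
  back <- read_fastq_tbl(path)
  expect_equal(back$id, tb$id)
  expect_equal(back$seq, tb$seq)
  expect_equal(back$qual, tb$qual)
})
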