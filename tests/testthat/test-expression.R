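# Read mapping, percentage tables, class aggregation, regressions.

toxin_table_path <- system.file("extdata", "chorr_toxin_clusters.tsv",
                           package = "toxdiverge")

test_that("reads map to their unique source window at the identity threshold", {
  set.seed(51)
  tr <- c(T1 = toxdiverge:::random_nt(400), T2 = toxdiverge:::random_nt(400))
  read <- substr(tr[["T1"]], 101, 200)
  m <- map_reads(read, tr)
  expect_equal(m$counts$count[m$counts$transcript == "T1"], 1L)
  expect_equal(m$n_assigned, 1L)
  # 8 mismatches in 100 nt: identity 0.92 < 0.95 -> unmapped
  ch <- strsplit(read, "")[[1]]
  idx <- seq(5, 96, length.out = 8)
  ch[idx] <- chartr("ACGT", "GTAC", ch[idx])
  m2 <- map_reads(paste(ch, collapse = ""), tr)
  expect_equal(m2$n_unmapped, 1L)
  expect_equal(sum(m2$counts$count), 0L)
})

test_that("ambiguous reads are tallied, never assigned, and totals balance", {
  set.seed(52)
  shared <- toxdiverge:::random_nt(300)
  tr <- c(C1 = shared, C2 = shared, U = toxdiverge:::random_nt(300))
  reads <- c(substr(shared, 1, 100),          # ambiguous between C1/C2
             substr(tr[["U"]], 50, 149),      # unique
             toxdiverge:::random_nt(100))     # unmappable
  m <- map_reads(reads, tr)
  expect_equal(m$n_ambiguous, 1L)
  expect_equal(m$n_assigned, 1L)
  expect_equal(m$n_unmapped, 1L)
  expect_equal(m$n_assigned + m$n_ambiguous + m$n_unmapped, m$n_reads)
})

test_that("mapped fractions track true abundances on simulated data", {
  cfg <- sim_config(n_read_pairs = 3000, error_rate = 0, seed = 53)
  set.seed(53)
  tr <- c(H = toxdiverge:::random_nt(500), L = toxdiverge:::random_nt(500))
  rd <- simulate_reads(tr, c(0.9, 0.1), cfg)
  merged <- merge_read_pairs(rd)$merged
  m <- map_reads(merged$seq, tr)
  frac <- m$counts$count[m$counts$transcript == "H"] / sum(m$counts$count)
  sd3 <- 3 * sqrt(0.9 * 0.1 / 3000)
  expect_lt(abs(frac - 0.9), sd3)
})

test_that("count-to-percentage conversion follows the printed-table layout", {
  counts <- tibble::tibble(cluster = c("SVSP-1", "PLA2-1", "NT-1"),
                           count = c(50, 50, 60),
                           class = c("toxin", "toxin", "nontoxin"))
  out <- counts_to_percentages(counts, total_reads = 200)
  expect_equal(out$pct_total, c(25, 25, 30))
  expect_equal(out$pct_toxin, c(50, 50, NA))
  single <- counts_to_percentages(
    tibble::tibble(cluster = "X", count = 10, class = "toxin"),
    total_reads = 100)
  expect_equal(single$pct_toxin, 100)
  expect_error(counts_to_percentages(
    tibble::tibble(cluster = "X", count = 0, class = "toxin")), "zero mapped")
})

test_that("class aggregation of the printed toxin table gives the known shares", {
  t1 <- read_expression_table(toxin_table_path)
  cs <- summarize_toxin_classes(t1)
  get <- function(cl) cs$pct_toxin[cs$class == cl]
  expect_equal(round(get("SVSP"), 1), 58.2)
  expect_equal(round(get("PLA2"), 1), 22.8)
  expect_equal(round(get("BPP"), 1), 12.5)
  expect_equal(cs$n_clusters[cs$class == "SVSP"], 11L)
  expect_equal(cs$n_clusters[cs$class == "PLA2"], 9L)
  # one-class table degenerates to 100%
  one <- tibble::tibble(cluster = c("SVSP-1", "SVSP-2"),
                        pct_total = c(10, 5), pct_toxin = c(60, 40))
  expect_equal(summarize_toxin_classes(one)$pct_toxin, 100)
})

test_that("toxin read fraction is recovered from the percentage ratio", {
  t1 <- read_expression_table(toxin_table_path)
  tf <- toxin_fraction_from_table(t1)
  expect_equal(round(tf$fraction, 1), 40.9)
  # degenerate: pct_total == pct_toxin means toxins are all reads
  all_tox <- tibble::tibble(cluster = c("a", "b"),
                            pct_total = c(60, 40), pct_toxin = c(60, 40))
  expect_equal(toxin_fraction_from_table(all_tox)$fraction, 100)
  # algebraic identity on a table built from raw counts
  counts <- tibble::tibble(cluster = paste0("SVSP-", 1:4),
                           count = c(400, 300, 200, 100),
                           class = "toxin")
  tab <- counts_to_percentages(counts, total_reads = 4000)
  expect_equal(toxin_fraction_from_table(tab)$fraction,
               100 * 1000 / 4000, tolerance = 1e-6)
})

test_that("cross-species regression recovers exact linear relations", {
  x <- c(1, 2, 3, 4, 5, 6)
  r1 <- cross_species_regression(x, x, outlier_policy = "none")
  t1 <- tidy(r1)
  expect_equal(t1$slope, 1, tolerance = 1e-12)
  expect_equal(t1$intercept, 0, tolerance = 1e-9)
  expect_equal(t1$r_squared, 1)
  r2 <- cross_species_regression(x, 2 * x + 3, outlier_policy = "none")
  t2 <- tidy(r2)
  expect_equal(t2$slope, 2, tolerance = 1e-12)
  expect_equal(t2$intercept, 3, tolerance = 1e-9)
  expect_error(cross_species_regression(rep(2, 5), 1:5), "zero variance")
})

test_that("a single dominant outlier is detected and removed by Cook's distance", {
  set.seed(54)
  x <- rlnorm(80, log(100), 1)
  y <- x * rlnorm(80, 0, 0.1)
  x[1] <- 5000; y[1] <- 15000  # protein-disulfide-isomerase-style point
  r <- cross_species_regression(x, y, ids = c("PDI", paste0("g", 2:80)))
  expect_equal(r$removed, "PDI")
  expect_lt(abs(tidy(r)$slope[2] - 1), 0.1)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("length-count association handles degenerate and perfect fits", {
  lens <- c(100, 200, 300, 400, 500)
  flat <- length_count_association(lens, rep(7, 5))
  expect_equal(flat$f_statistic, 0)
  expect_equal(flat$p_value, 1)
  prop <- length_count_association(lens, 3 * lens)
  expect_lt(prop$p_value, 1e-12)
  expect_equal(prop$df1, 1)
  expect_equal(prop$df2, 3)
})

test_that("length-count p-values are calibrated under the null", {
  set.seed(55)
  nsim <- 400
  p <- vapply(seq_len(nsim), function(i) {
    length_count_association(runif(50, 200, 3000), rpois(50, 40))$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nsim) + 0.01)
})
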