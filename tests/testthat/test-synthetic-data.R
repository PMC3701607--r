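# The synthetic two-species transcriptome generator.

test_that("config invariants are enforced", {
  expect_error(sim_config(coding_length = 100), "coding_length")
  expect_error(sim_config(fragment_length = 210, read_length = 100))
  expect_error(sim_config(error_rate = -0.1))
  expect_error(sim_config(toxin_families = list(BAD = list(
    birth = -1, death = 0, omega = 0.5))), "nonviable")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_lt(cfg$fragment_length, 2 * cfg$read_length)
})

test_that("config round-trips through YAML unchanged", {
  cfg <- sim_config(n_nontoxins = 42, seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("a zero-rate family tracks the species tree with no events", {
  cfg <- sim_config()
  set.seed(71)
  fam <- simulate_gene_family(cfg, list(birth = 0, death = 0, omega = 0.5),
                              name = "F0")
  expect_equal(length(fam$tree$tip.label), 3)
  expect_setequal(unname(fam$leaf_species), c("A", "B", "Out"))
  expect_equal(sum(fam$true_events$duplications), 0)
  expect_equal(sum(fam$true_events$losses), 0)
  rec <- reconcile(fam$tree, ape::read.tree(text = cfg$species_tree),
                   stats::setNames(unname(fam$leaf_species),
                                   names(fam$leaf_species)))
  expect_equal(rec$duplications, 0)
  expect_equal(rec$losses, 0)
})

test_that("pure-birth copy numbers match the branching-process expectation", {
  # E[n(t)] = exp((b - d) t); b = 1, d = 0, t = 0.5 on a single branch
  set.seed(72)
  env <- new.env(); env$D <- list(); env$L <- list()
  n <- vapply(1:2000, function(i) {
    res <- toxdiverge:::sim_bd_branch(0.5, 1, 0, env, "x")
    length(toxdiverge:::bd_branch_ends(res))
  }, numeric(1))
  mc_se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - exp(0.5)), 3 * mc_se)
})

test_that("nonviable families fail with the family named", {
  cfg <- sim_config()
  set.seed(73)
  expect_error(
    simulate_gene_family(cfg, list(birth = 0, death = 500, omega = 0.5),
                         name = "DOOMED", max_resample = 10),
    "DOOMED")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config()
  set.seed(74)
  f1 <- simulate_gene_family(cfg, list(birth = 10, death = 3, omega = 1),
                             name = "F")
  set.seed(74)
  f2 <- simulate_gene_family(cfg, list(birth = 10, death = 3, omega = 1),
                             name = "F")
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  ds1 <- simulate_transcriptomes(sim_config(n_nontoxins = 10,
                                            n_read_pairs = 50, seed = 75))
  ds2 <- simulate_transcriptomes(sim_config(n_nontoxins = 10,
                                            n_read_pairs = 50, seed = 75))
  expect_identical(ds1$transcripts$seq, ds2$transcripts$seq)
  expect_identical(ds1$reads[["A"]]$seq1, ds2$reads[["A"]]$seq1)
})

test_that("zero-length branches leave sequences identical to the ancestor", {
  tr <- ape::read.tree(text = "(x:0,y:0);")
  seqs <- evolve_codon_sequences(tr, 0.5, 2, 90)
  expect_equal(seqs[["x"]], seqs[["y"]])
  expect_error(evolve_codon_sequences(tr, 0.5, 2, 91), "multiple of 3")
})

test_that("evolved coding sequences never contain in-frame stops", {
  set.seed(76)
  tr <- ape::read.tree(text = "((x:0.3,y:0.3):0.2,z:0.5);")
  seqs <- evolve_codon_sequences(tr, 1.5, 2, 600)
  for (s in seqs) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("expression tables are normalised and exactly conserved at zero noise", {
  cfg0 <- sim_config(expression_noise_sd = 0, toxin_divergence = 0)
  set.seed(77)
  ex <- simulate_expression(cfg0)
  sums <- tapply(ex$abundance_pct, ex$species, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  nt <- ex[ex$class == "nontoxin", ]
  a <- nt$abundance_pct[nt$species == "A"]
  b <- nt$abundance_pct[nt$species == "B"]
  fit <- tidy(cross_species_regression(a, b, outlier_policy = "none"))
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
})

test_that("nontoxin expression conservation decays with the noise level", {
  cfg <- sim_config(n_nontoxins = 300)
  set.seed(78)
  mean_r2 <- vapply(c(0.1, 0.5, 1.0), function(sd) {
    cfg$expression_noise_sd <- sd
    mean(vapply(1:20, function(i) {
      ex <- simulate_expression(cfg)
      nt <- ex[ex$class == "nontoxin", ]
      a <- nt$abundance_pct[nt$species == "A"]
      b <- nt$abundance_pct[nt$species == "B"]
      summary(stats::lm(b ~ a))$r.squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("read pairs overlap by the configured amount and carry matched phred", {
  cfg <- sim_config(n_read_pairs = 200, error_rate = 0.01, seed = 79)
  set.seed(79)
  tr <- c(T1 = toxdiverge:::random_nt(400))
  rd <- simulate_reads(tr, 1, cfg)
  expect_equal(unique(nchar(rd$seq1)), cfg$read_length)
  expect_equal(unique(unlist(rd$qual1)), 20L)  # -10 log10(0.01)
  # short transcripts are skipped with a warning
  expect_warning(
    simulate_reads(c(S = toxdiverge:::random_nt(100), T1 = tr[[1]]),
                   c(0.5, 0.5), cfg),
    "skipped")
})

test_that("injected error rate matches the nominal rate", {
  cfg <- sim_config(n_read_pairs = 20000, error_rate = 0.01, seed = 80)
  set.seed(80)
  tr <- c(T1 = toxdiverge:::random_nt(500))
  rd <- simulate_reads(tr, 1, cfg)
  frag <- substring(tr[[1]], rd$start, rd$start + cfg$fragment_length - 1)
  true1 <- substring(frag, 1, cfg$read_length)
  true2 <- vapply(substring(frag, cfg$fragment_length - cfg$read_length + 1,
                            cfg$fragment_length),
                  toxdiverge:::revcomp, character(1), USE.NAMES = FALSE)
  mm <- function(x, y) {
    sum(vapply(seq_along(x), function(i) {
      sum(strsplit(x[i], "")[[1]] != strsplit(y[i], "")[[1]])
    }, numeric(1)))
  }
  total_mm <- mm(rd$seq1, true1) + mm(rd$seq2, true2)
  total_bases <- 2 * nrow(rd) * cfg$read_length
  expect_gte(total_mm / total_bases, 0.009)
  expect_lte(total_mm / total_bases, 0.011)
})

test_that("read sampling tracks abundance within binomial error", {
  cfg <- sim_config(n_read_pairs = 20000, error_rate = 0, seed = 81)
  set.seed(81)
  tr <- c(H = toxdiverge:::random_nt(400), L = toxdiverge:::random_nt(400))
  rd <- simulate_reads(tr, c(0.9, 0.1), cfg)
  frac <- mean(rd$transcript == "H")
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / nrow(rd)))
})

test_that("written datasets use standard formats with ground-truth sidecar", {
  ds <- simulate_transcriptomes(sim_config(n_nontoxins = 8,
                                           n_read_pairs = 30, seed = 82))
  dir <- tempfile("simout")
  write_simulation(ds, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "A_transcripts.fasta"))
  expect_true(all(grepl("\\|class=(toxin|nontoxin)", names(fa))))
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_true(all(c("species", "id", "class", "omega", "abundance_pct")
                  %in% names(truth)))
  r1 <- read_fastq_tbl(file.path(dir, "A_R1.fastq"))
  expect_equal(nrow(r1), 30)
  tree <- ape::read.tree(file.path(dir, "species_tree.nwk"))
  expect_equal(length(tree$tip.label), 3)
})
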