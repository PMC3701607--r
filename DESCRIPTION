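Package: toxdiverge
Title: Comparative Venom-Gland Transcriptomics of Toxin Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for contrasting toxin and nontoxin
    molecular evolution between two congeneric snake venom-gland
    transcriptomes. Provides merging of 3'-overlapping read pairs with
    phred-quality recombination, k-mer-seeded read mapping with
    percentage-of-reads expression profiling and toxin-class summaries,
    single-linkage clustering of toxin coding sequences at a nucleotide
    divergence threshold, dual (nucleotide and protein) reciprocal-best-hit
    orthology with Karlin-Altschul E-value statistics, Nei-Gojobori (1986)
    pairwise dS/dN/dN-dS estimation with Jukes-Cantor correction and the
    associated dS filters, nontoxin null-distribution exceedance analysis
    with Wilcoxon rank-sum comparisons, duplication-loss parsimony
    reconciliation of gene trees against a three-taxon species tree, and a
    fully seeded synthetic two-species transcriptome generator with known
    gene-family histories, omega values, expression profiles and paired
    reads for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
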