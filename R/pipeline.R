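# End-to-end orchestration: simulate (or load) a two-species dataset,
# merge reads, map, profile expression, find orthologs, estimate rates,
# run the exceedance statistics, reconcile toxin families, and write
# paper-style reports with a hash manifest.

#' Pipeline configuration
#'
#' Bundles the synthetic-data config with every stage threshold.
#'
#' @param sim a [sim_config()]
#' @param min_overlap,max_mismatch_frac read-merging thresholds
#' @param min_identity read-mapping identity threshold
#' @param cluster_threshold strict p-distance threshold for toxin
#'   clustering
#' @param max_gapped codon-alignment gap filter (nucleotide positions)
#' @param e_cutoff reciprocal-best-hit E-value cutoff
#' @param q null-distribution quantile for exceedance analysis
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(sim = sim_config(),
                            min_overlap = 10, max_mismatch_frac = 0.1,
                            min_identity = 0.95,
                            cluster_threshold = 0.01,
                            max_gapped = 24,
                            e_cutoff = 1e-6,
                            q = 0.95) {
  stopifnot(min_overlap >= 1, max_mismatch_frac >= 0, max_mismatch_frac < 1,
            min_identity > 0, min_identity <= 1,
            cluster_threshold >= 0, max_gapped >= 0,
            e_cutoff > 0, q > 0, q < 1)
  structure(list(sim = sim, min_overlap = min_overlap,
                 max_mismatch_frac = max_mismatch_frac,
                 min_identity = min_identity,
                 cluster_threshold = cluster_threshold,
                 max_gapped = max_gapped, e_cutoff = e_cutoff, q = q),
            class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Stages run in dependency order: simulate, merge read pairs, map
#' composite reads, build the clustered toxin expression table, dual
#' reciprocal-best-hit orthology, NG86 rates with the gap and dS filters,
#' exceedance statistics, gene-family reconciliation, and report writing.
#' Every output file is md5-hashed into `manifest.tsv`; rerunning with the
#' same config (and its seed) reproduces identical hashes.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory for the run
#' @return list with the per-stage results (`dataset`, `merge`, `mapping`,
#'   `expression`, `class_summary`, `orthologs`, `rates`, `reports`,
#'   `regression`, `reconciliations`, `manifest`)
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = file.path(tempdir(), "toxdiverge_run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_transcriptomes(config$sim)
  write_simulation(ds, file.path(out_dir, "inputs"))

  # --- merge and map per ingroup species
  merge_res <- list(); mapping <- list()
  for (sp in c("A", "B")) {
    merge_res[[sp]] <- merge_read_pairs(
      ds$reads[[sp]], config$min_overlap, config$max_mismatch_frac)
    sub <- ds$transcripts[ds$transcripts$species == sp, , drop = FALSE]
    mapping[[sp]] <- map_reads(
      merge_res[[sp]]$merged$seq,
      stats::setNames(sub$seq, sub$id),
      min_identity = config$min_identity)
  }

  # --- clustered toxin expression table for species A
  trA <- ds$transcripts[ds$transcripts$species == "A", , drop = FALSE]
  toxA <- trA[trA$class == "toxin", , drop = FALSE]
  clusters <- if (nrow(toxA) > 0) {
    cluster_sequences(stats::setNames(toxA$cds, toxA$id),
                      threshold = config$cluster_threshold)
  } else NULL
  countsA <- mapping[["A"]]$counts
  cl_of <- if (!is.null(clusters)) {
    stats::setNames(clusters$representative, clusters$name)
  } else character(0)
  countsA$cluster <- ifelse(countsA$transcript %in% names(cl_of),
                            cl_of[countsA$transcript], countsA$transcript)
  countsA$class <- trA$class[match(countsA$transcript, trA$id)]
  cluster_counts <- countsA |>
    dplyr::group_by(.data$cluster, .data$class) |>
    dplyr::summarise(count = sum(.data$count),
                     cluster_size = dplyr::n(), .groups = "drop")
  lenA <- stats::setNames(nchar(trA$seq), trA$id)
  cluster_counts$length <- unname(lenA[cluster_counts$cluster])
  expr_table <- counts_to_percentages(
    cluster_counts, total_reads = nrow(merge_res[["A"]]$merged)) |>
    dplyr::arrange(dplyr::desc(.data$pct_total)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class_summary <- summarize_toxin_classes(expr_table)

  # --- orthology, rates, statistics
  mk_set <- function(sp) {
    sub <- ds$transcripts[ds$transcripts$species == sp, , drop = FALSE]
    tibble::tibble(id = sub$id, seq = sub$seq, cds = sub$cds,
                   class = sub$class)
  }
  orth <- reciprocal_best_hits(mk_set("A"), mk_set("B"),
                               e_cutoff = config$e_cutoff)
  cdsA <- stats::setNames(ds$transcripts$cds, ds$transcripts$id)
  pairs <- orth |>
    dplyr::mutate(cds_a = unname(cdsA[.data$id_a]),
                  cds_b = unname(cdsA[.data$id_b]))
  rates <- rates_table(pairs, max_gapped = config$max_gapped)
  reports <- rate_exceedance_reports(rates, q = config$q)

  # --- cross-species nontoxin expression comparison (toxins filtered)
  ntp <- pairs[!is.na(pairs$class) & pairs$class == "nontoxin", , drop = FALSE]
  cntA <- stats::setNames(mapping[["A"]]$counts$count,
                          mapping[["A"]]$counts$transcript)
  cntB <- stats::setNames(mapping[["B"]]$counts$count,
                          mapping[["B"]]$counts$transcript)
  regression <- if (nrow(ntp) >= 3) {
    cross_species_regression(unname(cntA[ntp$id_a]), unname(cntB[ntp$id_b]),
                             ids = ntp$id_a)
  } else NULL

  # --- reconciliation of every toxin family against the species tree
  stree <- ape::read.tree(text = config$sim$species_tree)
  recs <- lapply(ds$families, function(fam) {
    map <- stats::setNames(unname(fam$leaf_species), names(fam$leaf_species))
    if (length(fam$tree$tip.label) < 2) return(NULL)
    reconcile(fam$tree, stree, map)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]

  manifest <- write_report(expr_table, class_summary, reports, rates,
                           regression, recs, out_dir)
  list(dataset = ds, merge = merge_res, mapping = mapping,
       expression = expr_table, class_summary = class_summary,
       clusters = clusters, orthologs = orth, rates = rates,
       reports = reports, regression = regression,
       reconciliations = recs, manifest = manifest, out_dir = out_dir)
}

#' Write the publication-style reports for a pipeline run
#'
#' Emits the ranked toxin expression table (ranked-cluster layout, percentages to
#' three decimals), the toxin-class summary, the rates table, and a JSON
#' stats report (means, thresholds, exceedance counts and expected counts,
#' test p-values, regression fits), then hashes every file into
#' `manifest.tsv`.
#'
#' @param expr_table expression tibble (with `rank`, `cluster`,
#'   `cluster_size`, `length`, `pct_total`, `pct_toxin`)
#' @param class_summary from [summarize_toxin_classes()]
#' @param reports from [rate_exceedance_reports()]
#' @param rates rates tibble
#' @param regression an `xspecies_regression` or NULL
#' @param reconciliations list of `reconciliation` objects
#' @param out_dir output directory
#' @return manifest tibble (file, md5), invisibly written to
#'   `manifest.tsv`
#' @export
write_report <- function(expr_table, class_summary, reports, rates,
                         regression, reconciliations, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tox <- expr_table[!is.na(expr_table$pct_toxin), , drop = FALSE] |>
    dplyr::arrange(dplyr::desc(.data$pct_total))
  t1 <- tibble::tibble(
    rank = seq_len(nrow(tox)),
    cluster = tox$cluster,
    cluster_size = tox$cluster_size,
    length = tox$length,
    pct_total = sprintf("%.3f", tox$pct_total),
    pct_toxin = sprintf("%.3f", tox$pct_toxin))
  utils::write.table(t1, file.path(out_dir, "toxin_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cs <- class_summary |>
    dplyr::mutate(pct_total = round(.data$pct_total, 1),
                  pct_toxin = round(.data$pct_toxin, 1))
  utils::write.table(cs, file.path(out_dir, "class_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rates, file.path(out_dir, "rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stats_out <- list()
  for (nm in names(reports)) {
    r <- reports[[nm]]
    tox_mean <- mean(r$toxin_values$value)
    non_mean <- mean(r$nontoxin_values)
    stats_out[[nm]] <- list(
      statistic = r$statistic, threshold = r$threshold,
      n_toxins = r$n_toxins, n_nontoxins = r$n_nontoxins,
      toxin_mean = tox_mean, nontoxin_mean = non_mean,
      observed_exceedances = r$observed, expected_exceedances = r$expected,
      binomial_p = r$binomial_p, wilcoxon_p = r$wilcoxon$p_value)
  }
  if (!is.null(regression)) {
    stats_out$regression <- xspec_stats(regression$full)
    if (!is.null(regression$refit)) {
      stats_out$regression_refit <- c(xspec_stats(regression$refit),
                                      list(removed = regression$removed))
    }
  }
  if (length(reconciliations) > 0) {
    stats_out$reconciliation <- lapply(reconciliations, function(r) {
      list(duplications = r$duplications, losses = r$losses)
    })
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- tibble::tibble(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
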