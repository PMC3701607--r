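# Read mapping, percentage-of-reads expression profiling, toxin-class
# aggregation, and cross-species nontoxin expression comparison.

# Known toxin-class prefixes for cluster names (longest match wins, so
# SVMPIII and SVMPI both collapse to SVMP).
TOXIN_CLASSES <- c("SVMP", "SVSP", "PLA2", "BPP", "CTL", "CRISP", "CREGF",
                   "GC", "HYAL", "KUN", "LAAO", "MYO", "NGF", "NUC", "NF",
                   "PDE", "VEGF", "VESP", "VF")

toxin_class_of <- function(cluster_names) {
  classes <- TOXIN_CLASSES[order(nchar(TOXIN_CLASSES), decreasing = TRUE)]
  out <- vapply(strsplit(cluster_names, "[-_]"), function(tokens) {
    for (tok in tokens) {
      for (cl in classes) {
        if (startsWith(tok, cl)) return(cl)
      }
    }
    NA_character_
  }, character(1))
  if (anyNA(out)) {
    message("unknown toxin-class prefix bucketed as 'other': ",
            paste(unique(cluster_names[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- "other"
  }
  out
}

#' Map composite reads to transcripts by k-mer seeding
#'
#' Each read contributes seed k-mers (from its start, middle and end);
#' seeds hitting the transcript index propose (transcript, offset)
#' placements, each evaluated by ungapped comparison across the whole
#' read. Identity is matching bases / read length. A read is assigned to
#' the unique best transcript with identity >= `min_identity`; equal-best
#' placements on distinct transcripts count as ambiguous and are not
#' assigned.
#'
#' @param reads character vector of read sequences (composite reads)
#' @param transcripts named character vector of transcript sequences
#' @param min_identity identity threshold in (0, 1] (default 0.95)
#' @param k seed length (default 15)
#' @return list with `counts` (tibble: `transcript`, `count`, including
#'   zero rows), `n_assigned`, `n_ambiguous`, `n_unmapped`, `n_reads`
#' @export
map_reads <- function(reads, transcripts, min_identity = 0.95, k = 15L) {
  stopifnot(length(transcripts) > 0, min_identity > 0, min_identity <= 1)
  if (is.null(names(transcripts))) stop("transcripts must be named")
  transcripts <- toupper(transcripts)
  # index: k-mer -> transcript index and 1-based position
  keys <- character(0); tix <- integer(0); tpos <- integer(0)
  for (i in seq_along(transcripts)) {
    s <- transcripts[[i]]
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    keys <- c(keys, km)
    tix <- c(tix, rep.int(i, length(km)))
    tpos <- c(tpos, seq_along(km))
  }
  index <- split(seq_along(keys), keys)
  tchars <- lapply(transcripts, function(s) strsplit(s, "")[[1]])
  tlen <- nchar(transcripts)
  n_assigned <- 0L; n_ambiguous <- 0L; n_unmapped <- 0L
  counts <- stats::setNames(integer(length(transcripts)), names(transcripts))
  for (r in reads) {
    r <- toupper(r)
    rl <- nchar(r)
    if (rl < k) { n_unmapped <- n_unmapped + 1L; next }
    starts <- unique(pmax(1L, c(1L, (rl - k) %/% 2L + 1L, rl - k + 1L)))
    cand <- list()
    for (st in starts) {
      hit <- index[[substr(r, st, st + k - 1L)]]
      for (h in hit) {
        off <- tpos[h] - st  # transcript pos of read base 1, minus 1
        key <- paste0(tix[h], "@", off)
        cand[[key]] <- c(tix[h], off)
      }
    }
    if (length(cand) == 0L) { n_unmapped <- n_unmapped + 1L; next }
    rc <- strsplit(r, "")[[1]]
    best_id <- 0; best_tr <- integer(0)
    for (cd in cand) {
      ti <- cd[1]; off <- cd[2]
      if (off < 0L || off + rl > tlen[ti]) next  # read must lie within
      frag <- tchars[[ti]][(off + 1L):(off + rl)]
      ident <- sum(frag == rc) / rl
      if (ident > best_id + 1e-12) { best_id <- ident; best_tr <- ti }
      else if (abs(ident - best_id) <= 1e-12) best_tr <- union(best_tr, ti)
    }
    if (best_id < min_identity || length(best_tr) == 0L) {
      n_unmapped <- n_unmapped + 1L
    } else if (length(best_tr) > 1L) {
      n_ambiguous <- n_ambiguous + 1L
    } else {
      n_assigned <- n_assigned + 1L
      counts[best_tr] <- counts[best_tr] + 1L
    }
  }
  list(counts = tibble::tibble(transcript = names(counts),
                               count = unname(counts)),
       n_assigned = n_assigned, n_ambiguous = n_ambiguous,
       n_unmapped = n_unmapped, n_reads = length(reads))
}

#' Convert read counts to percentage-of-reads expression values
#'
#' `pct_total` is the percentage of all input reads mapping to the row;
#' `pct_toxin` the percentage of toxin-assigned reads (toxin rows only).
#'
#' @param counts tibble with `transcript` (or `cluster`), `count`, and
#'   `class` (`"toxin"`/`"nontoxin"`)
#' @param total_reads total number of input reads (defaults to
#'   `sum(count)`, i.e. treating all reads as mapped)
#' @return the input with `pct_total` and `pct_toxin` columns added
#' @export
counts_to_percentages <- function(counts, total_reads = sum(counts$count)) {
  stopifnot(all(c("count", "class") %in% names(counts)))
  if (sum(counts$count) == 0) stop("zero mapped reads")
  toxin_total <- sum(counts$count[counts$class == "toxin"])
  counts |>
    dplyr::mutate(
      pct_total = 100 * .data$count / total_reads,
      pct_toxin = dplyr::if_else(.data$class == "toxin" & toxin_total > 0,
                                 100 * .data$count / toxin_total, NA_real_)
    )
}

#' Aggregate a toxin expression table by toxin class
#'
#' Cluster names carry a class prefix (SVSP-1a, PLA2-2, ...); per-class
#' sums of the two percentage columns are returned, ordered by share of
#' toxin reads. Unknown prefixes bucket as "other" with a message.
#'
#' @param table expression tibble with `cluster` (name), `pct_total`,
#'   `pct_toxin`; nontoxin rows (NA `pct_toxin`) are ignored
#' @return tibble: `class`, `n_clusters`, `pct_total`, `pct_toxin`
#' @export
summarize_toxin_classes <- function(table) {
  tox <- table[!is.na(table$pct_toxin), , drop = FALSE]
  tox$class <- toxin_class_of(tox$cluster)
  tox |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_clusters = dplyr::n(),
                     pct_total = sum(.data$pct_total),
                     pct_toxin = sum(.data$pct_toxin), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$pct_toxin))
}

#' Fraction of all reads mapping to toxins, recovered from a printed table
#'
#' Row-wise, `pct_total / pct_toxin` equals the toxin share of all reads;
#' the median over rows is reported (x100), and rows deviating from it by
#' more than 1% relative are flagged.
#'
#' @param table expression tibble with `pct_total` and `pct_toxin`
#' @return list with `fraction` (percent of all reads) and `inconsistent`
#'   (cluster names deviating > 1% relative from the median ratio)
#' @export
toxin_fraction_from_table <- function(table) {
  tox <- table[!is.na(table$pct_toxin), , drop = FALSE]
  usable <- tox$pct_toxin > 0
  if (any(!usable)) {
    warning("skipping ", sum(!usable), " row(s) with zero pct_toxin")
    tox <- tox[usable, , drop = FALSE]
  }
  stopifnot(nrow(tox) > 0)
  ratio <- tox$pct_total / tox$pct_toxin
  med <- stats::median(ratio)
  inconsistent <- tox$cluster[abs(ratio - med) / med > 0.01]
  list(fraction = 100 * med, inconsistent = inconsistent)
}

#' Cross-species expression regression for shared nontoxins
#'
#' Ordinary least squares of species-y read counts on species-x read
#' counts for ortholog pairs. With `outlier_policy = "auto"` at most one
#' point — the largest Cook's distance, if it exceeds 4/n — is removed and
#' the model refit; both fits are reported. An explicit `exclude` vector
#' of pair identifiers is also honoured.
#'
#' @param x_counts,y_counts paired counts (n >= 3)
#' @param outlier_policy `"auto"`, `"none"`, or `"exclude"`
#' @param ids optional identifiers for the pairs
#' @param exclude identifiers to drop when `outlier_policy = "exclude"`
#' @return object of class `xspecies_regression` with `full` and
#'   `refit` lm fits, `removed` (ids), and tidy accessors via
#'   [generics::tidy()] / [generics::glance()]
#' @export
cross_species_regression <- function(x_counts, y_counts,
                                     outlier_policy = c("auto", "none", "exclude"),
                                     ids = NULL, exclude = character(0)) {
  outlier_policy <- match.arg(outlier_policy)
  stopifnot(length(x_counts) == length(y_counts), length(x_counts) >= 3)
  if (stats::var(x_counts) == 0) stop("zero variance in predictor counts")
  if (is.null(ids)) ids <- as.character(seq_along(x_counts))
  d <- tibble::tibble(id = ids, x = x_counts, y = y_counts)
  full <- stats::lm(y ~ x, data = d)
  removed <- character(0)
  refit <- NULL
  if (outlier_policy == "auto") {
    cd <- stats::cooks.distance(full)
    i <- which.max(cd)
    if (cd[i] > 4 / nrow(d)) {
      removed <- d$id[i]
      refit <- stats::lm(y ~ x, data = d[-i, , drop = FALSE])
    }
  } else if (outlier_policy == "exclude" && length(exclude) > 0) {
    keep <- !(d$id %in% exclude)
    removed <- d$id[!keep]
    refit <- stats::lm(y ~ x, data = d[keep, , drop = FALSE])
  }
  structure(list(full = full, refit = refit, removed = removed, data = d),
            class = "xspecies_regression")
}

xspec_stats <- function(fit) {
  s <- suppressWarnings(summary(fit))  # exact fits warn about perfection
  fstat <- s$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       f_statistic = unname(fstat[1]),
       df1 = unname(fstat[2]), df2 = unname(fstat[3]),
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)))
}

#' @export
print.xspecies_regression <- function(x, ...) {
  st <- xspec_stats(x$full)
  cat(sprintf("<xspecies_regression> n = %d: slope %.3g, intercept %.3g, R2 %.3g\n",
              nrow(x$data), st$slope, st$intercept, st$r_squared))
  if (!is.null(x$refit)) {
    st2 <- xspec_stats(x$refit)
    cat(sprintf("  after removing %s: slope %.3g, intercept %.3g, R2 %.3g\n",
                paste(x$removed, collapse = ", "),
                st2$slope, st2$intercept, st2$r_squared))
  }
  invisible(x)
}

#' Association between transcript length and read counts
#'
#' F-test of the simple linear regression of counts on length, df (1,
#' n - 2). Constant counts give F = 0, p = 1 rather than an error.
#'
#' @param lengths,counts numeric vectors (n >= 3)
#' @return list with `f_statistic`, `df1`, `df2`, `p_value`
#' @export
length_count_association <- function(lengths, counts) {
  stopifnot(length(lengths) == length(counts), length(lengths) >= 3)
  n <- length(lengths)
  if (stats::var(counts) == 0) {
    return(list(f_statistic = 0, df1 = 1, df2 = n - 2L, p_value = 1))
  }
  fit <- stats::lm(counts ~ lengths)
  s <- suppressWarnings(summary(fit))
  f <- s$fstatistic
  list(f_statistic = unname(f[1]), df1 = unname(f[2]), df2 = unname(f[3]),
       p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)))
}

#' Read a printed toxin expression table (ranked-cluster TSV)
#'
#' Columns: rank, cluster, cluster_size, length, pct_total, pct_toxin.
#'
#' @param path TSV path
#' @return tibble
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("rank", "cluster", "cluster_size", "length",
                 "pct_total", "pct_toxin")[seq_along(names(df))]
  if (is.character(df$length)) df$length <- as.numeric(gsub(",", "", df$length))
  tibble::as_tibble(df)
}
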