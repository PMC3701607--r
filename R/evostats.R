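# Nontoxin null distributions, 95th-percentile exceedance analysis, and
# Wilcoxon rank-sum comparisons of toxin vs nontoxin substitution rates.

#' Empirical percentile threshold
#'
#' Linear interpolation between order statistics (index `1 + (n - 1) q`,
#' i.e. [stats::quantile()] type 7).
#'
#' @param values numeric sample (at least one finite value)
#' @param q probability (default 0.95)
#' @return the threshold value
#' @export
percentile_threshold <- function(values, q = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values for percentile threshold")
  unname(stats::quantile(values, q, type = 7, names = FALSE))
}

#' Exceedance analysis of toxin values against a nontoxin null
#'
#' The threshold is the empirical `q`-quantile of the nontoxin values;
#' toxin values strictly greater than it count as exceedances. Under the
#' null hypothesis that toxins follow the nontoxin distribution the
#' expected count is `(1 - q) * n_toxins`; the exact binomial tail
#' probability of seeing at least the observed count is reported, along
#' with a Wilcoxon rank-sum comparison of the two samples.
#'
#' @param toxin_values,nontoxin_values numeric vectors (already filtered)
#' @param q null-quantile level (default 0.95)
#' @param statistic label carried into the report (e.g. `"dN/dS"`)
#' @return object of class `exceedance_report`: a list with `statistic`,
#'   `threshold`, `n_toxins`, `n_nontoxins`, `observed`, `expected`,
#'   `binomial_p`, `wilcoxon` (statistic and p), `toxin_values` (tibble
#'   with per-value `exceeds` flag) and `nontoxin_values`
#' @examples
#' r <- exceedance_analysis(rexp(29), rexp(200))
#' r$expected  # 1.45
#' @export
exceedance_analysis <- function(toxin_values, nontoxin_values, q = 0.95,
                                statistic = "value") {
  toxin_values <- toxin_values[is.finite(toxin_values)]
  nontoxin_values <- nontoxin_values[is.finite(nontoxin_values)]
  stopifnot(length(toxin_values) > 0, length(nontoxin_values) > 1)
  thr <- percentile_threshold(nontoxin_values, q)
  exceeds <- toxin_values > thr  # strict
  n <- length(toxin_values)
  observed <- sum(exceeds)
  expected <- (1 - q) * n
  binom_p <- stats::pbinom(observed - 1L, n, 1 - q, lower.tail = FALSE)
  w <- wilcoxon_rank_sum(toxin_values, nontoxin_values)
  structure(list(
    statistic = statistic,
    q = q,
    threshold = thr,
    n_toxins = n,
    n_nontoxins = length(nontoxin_values),
    observed = observed,
    expected = expected,
    binomial_p = binom_p,
    wilcoxon = w,
    toxin_values = tibble::tibble(value = toxin_values, exceeds = exceeds),
    nontoxin_values = nontoxin_values
  ), class = "exceedance_report")
}

#' @export
print.exceedance_report <- function(x, ...) {
  cat("<exceedance_report>", x$statistic, "\n")
  cat(sprintf("  null: n = %d nontoxins, %g%% threshold = %.4g\n",
              x$n_nontoxins, 100 * x$q, x$threshold))
  cat(sprintf("  toxins: %d of %d exceed (expected %.3g under the null)\n",
              x$observed, x$n_toxins, x$expected))
  cat(sprintf("  binomial tail P = %.3g; Wilcoxon W = %g, P = %.3g\n",
              x$binomial_p, x$wilcoxon$statistic, x$wilcoxon$p_value))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when `min(n, m) <= 8` with no ties; otherwise the
#' normal approximation with tie and continuity corrections (ties
#' mid-ranked). Thin wrapper over [stats::wilcox.test()] fixing that
#' policy.
#'
#' @param x,y numeric samples
#' @param two_sided two-sided alternative (default) or greater
#' @return list with `statistic` (W) and `p_value`
#' @export
wilcoxon_rank_sum <- function(x, y, two_sided = TRUE) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = if (two_sided) "two.sided" else "greater",
    exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Apply the dS acceptance windows to a rates table
#'
#' Pairs flagged `gap_excluded` never enter. The dS and dN analysis sets
#' drop pairs with `dS > 0.1` (spurious-ortholog guard); the dN/dS set
#' additionally drops pairs with `dS < 0.001` (unstable ratio).
#'
#' @param results rates tibble from [rates_table()]
#' @return list of tibbles `dnds_set`, `dn_set`, `ds_set`, plus a `counts`
#'   tibble of retained pairs per class and analysis
#' @export
apply_rate_filters <- function(results) {
  ok <- !results$gap_excluded & !is.na(results$dS) & !is.na(results$dN)
  base <- results[ok & !results$ds_too_large, , drop = FALSE]
  dnds <- base[!base$ds_too_small, , drop = FALSE]
  counts <- dplyr::bind_rows(
    dplyr::count(dnds, .data$class, name = "n_pairs") |>
      dplyr::mutate(analysis = "dN/dS"),
    dplyr::count(base, .data$class, name = "n_pairs") |>
      dplyr::mutate(analysis = "dN"),
    dplyr::count(base, .data$class, name = "n_pairs") |>
      dplyr::mutate(analysis = "dS")
  )
  list(dnds_set = dnds, dn_set = base, ds_set = base, counts = counts)
}

#' Toxin-vs-nontoxin exceedance reports for dN/dS, dN and dS
#'
#' Applies [apply_rate_filters()] and runs [exceedance_analysis()] for each
#' statistic with nontoxins as the null sample.
#'
#' @param results rates tibble from [rates_table()] with a `class` column
#'   of `"toxin"`/`"nontoxin"`
#' @param q null-quantile level (default 0.95)
#' @return named list of `exceedance_report` objects (`dnds`, `dn`, `ds`)
#' @export
rate_exceedance_reports <- function(results, q = 0.95) {
  f <- apply_rate_filters(results)
  pick <- function(tbl, col) {
    list(tox = tbl[[col]][tbl$class == "toxin"],
         non = tbl[[col]][tbl$class == "nontoxin"])
  }
  v1 <- pick(f$dnds_set, "omega")
  v2 <- pick(f$dn_set, "dN")
  v3 <- pick(f$ds_set, "dS")
  list(
    dnds = exceedance_analysis(v1$tox, v1$non, q, statistic = "dN/dS"),
    dn = exceedance_analysis(v2$tox, v2$non, q, statistic = "dN"),
    ds = exceedance_analysis(v3$tox, v3$non, q, statistic = "dS")
  )
}
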