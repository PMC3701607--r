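# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exceedance report
#'
#' One row per toxin value with its exceed flag.
#'
#' @param x an `exceedance_report`
#' @param ... unused
#' @return tibble with `statistic`, `value`, `exceeds`
#' @export
tidy.exceedance_report <- function(x, ...) {
  dplyr::mutate(x$toxin_values, statistic = x$statistic, .before = 1)
}

#' @rdname tidy.exceedance_report
#' @return for `glance`: a one-row tibble of the report's summary numbers
#' @export
glance.exceedance_report <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, q = x$q, threshold = x$threshold,
    n_toxins = x$n_toxins, n_nontoxins = x$n_nontoxins,
    observed = x$observed, expected = x$expected,
    binomial_p = x$binomial_p,
    wilcoxon_w = x$wilcoxon$statistic, wilcoxon_p = x$wilcoxon$p_value)
}

#' Tidy a cross-species expression regression
#'
#' One row per fit (full, and the refit after outlier removal when one was
#' made).
#'
#' @param x an `xspecies_regression`
#' @param ... unused
#' @return tibble with `fit`, `slope`, `intercept`, `r_squared`,
#'   `f_statistic`, `df1`, `df2`, `p_value`, `n`
#' @export
tidy.xspecies_regression <- function(x, ...) {
  row <- function(fit, label, n) {
    st <- xspec_stats(fit)
    tibble::tibble(fit = label, slope = st$slope, intercept = st$intercept,
                   r_squared = st$r_squared, f_statistic = st$f_statistic,
                   df1 = st$df1, df2 = st$df2, p_value = st$p_value, n = n)
  }
  out <- row(x$full, "full", nrow(x$data))
  if (!is.null(x$refit)) {
    out <- dplyr::bind_rows(
      out, row(x$refit, "outliers_removed", nrow(x$data) - length(x$removed)))
  }
  out
}

#' @rdname tidy.xspecies_regression
#' @return for `glance`: the final fit's one-row summary
#' @export
glance.xspecies_regression <- function(x, ...) {
  t <- tidy.xspecies_regression(x)
  t[nrow(t), , drop = FALSE]
}

#' Tidy a reconciliation
#'
#' @param x a `reconciliation`
#' @param ... unused
#' @return the per-node event tibble
#' @export
tidy.reconciliation <- function(x, ...) x$events

#' @rdname tidy.reconciliation
#' @return for `glance`: one row with `duplications` and `losses`
#' @export
glance.reconciliation <- function(x, ...) {
  tibble::tibble(duplications = x$duplications, losses = x$losses)
}
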