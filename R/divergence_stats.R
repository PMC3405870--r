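# Statistical tests: Welch two-sample t-tests on projection scores
# (selected vs remaining residues) and the pocket-ratio enrichment test.

.ALTERNATIVES <- c(two_sided = "two.sided", less = "less", greater = "greater")

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch--Satterthwaite degrees of
#' freedom (the default of R's `t.test`, which this wraps). A pooled-variance
#' Student test is available for sensitivity analysis.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alternative `"two_sided"`, `"less"` (mean of `x` smaller) or
#'   `"greater"`.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return An object of class `test_result`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `alternative`, `n1`, `n2`, `means`.
#' @export
welch_t_test <- function(x, y, alternative = c("two_sided", "less", "greater"),
                         var_equal = FALSE) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate-sample error: both samples have zero variance")
  tt <- stats::t.test(x, y, alternative = .ALTERNATIVES[[alternative]],
                      var.equal = var_equal)
  structure(list(t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 alternative = alternative,
                 n1 = length(x), n2 = length(y),
                 means = c(mean(x), mean(y))),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("Welch t-test (%s): t = %.4g, df = %.4g, p = %.4g\n",
              x$alternative, x$t_statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("  n = %d vs %d, means %.4g vs %.4g\n",
              x$n1, x$n2, x$means[1L], x$means[2L]))
  invisible(x)
}

#' Spatial-bias test on projection scores
#'
#' Compares the axis-projection scores of residues at selected sites against
#' the remaining residues. The null hypothesis is equal means; the one-sided
#' alternative `"less"` encodes intracellular bias of the selected sites
#' (their mean projection is smaller, i.e. more cytosolic).
#'
#' @param proj a `projection_result` with `selected` flags set (see
#'   [mark_selected_residues()]).
#' @param alternative passed to [welch_t_test()].
#' @return A `test_result`.
#' @export
projection_bias_test <- function(proj,
                                 alternative = c("two_sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  sel <- proj$score[proj$selected]
  rem <- proj$score[!proj$selected]
  if (length(sel) < 2L)
    stop("fewer than 2 selected residues projected onto the structure; ",
         "check the selection quantile and the reference mapping")
  if (length(rem) < 2L)
    stop("fewer than 2 remaining residues")
  welch_t_test(sel, rem, alternative)
}

#' Pocket-enrichment ratio test across comparisons
#'
#' Each comparison contributes the ratio of pocket-located selected sites to
#' all selected sites; the two sets of ratios (e.g. decoy-receptor vs
#' viral-receptor comparisons) are compared with a Welch t-test, treating the
#' ratios as plain real samples.
#'
#' @param pocket_counts_a,pocket_counts_b integer vectors: pocket-site counts
#'   per comparison for each side.
#' @param totals_a,totals_b integer vectors of total selected sites per
#'   comparison (element-wise >= the pocket counts, all positive).
#' @param alternative `"less"` means side A's ratios are smaller.
#' @return A `test_result`.
#' @export
pocket_enrichment_test <- function(pocket_counts_a, totals_a,
                                   pocket_counts_b, totals_b,
                                   alternative = c("less", "greater",
                                                   "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(pocket_counts_a) != length(totals_a) ||
      length(pocket_counts_b) != length(totals_b))
    stop("counts and totals differ in length")
  if (any(totals_a <= 0) || any(totals_b <= 0))
    stop("all totals must be positive")
  if (any(pocket_counts_a > totals_a) || any(pocket_counts_b > totals_b))
    stop("pocket counts exceed totals")
  if (length(totals_a) < 2L || length(totals_b) < 2L)
    stop("at least 2 comparisons per side required")
  welch_t_test(pocket_counts_a / totals_a, pocket_counts_b / totals_b,
               alternative)
}

#' Tabulate a set of test results
#'
#' Collects named `test_result` objects (one per comparison) into a tidy
#' data.frame — one row per comparison with its t statistic, degrees of
#' freedom and p-value — suitable for reporting or writing as TSV.
#'
#' @param results named list of `test_result` objects.
#' @return data.frame with columns `comparison`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `alternative`.
#' @export
test_results_table <- function(results) {
  stopifnot(length(results) > 0, !is.null(names(results)))
  data.frame(comparison = names(results),
             t_statistic = vapply(results, `[[`, 0, "t_statistic"),
             degrees_of_freedom = vapply(results, `[[`, 0,
                                         "degrees_of_freedom"),
             p_value = vapply(results, `[[`, 0, "p_value"),
             alternative = vapply(results, `[[`, "", "alternative"),
             row.names = NULL)
}

#' Path to the packaged pocket-site count table
#'
#' Counts of pocket-located divergent sites and total selected sites for the
#' ten published chemokine-receptor comparisons (five decoy-receptor groups,
#' five viral-receptor groups), used by the pocket-enrichment example.
#'
#' @return File path within the installed package.
#' @export
pocket_counts_path <- function() {
  system.file("extdata", "pocket_site_counts.tsv", package = "klsite",
              mustWork = TRUE)
}
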