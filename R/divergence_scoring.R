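# Column-wise symmetric Kullback-Leibler information between the two groups'
# regularized compositions, top-quantile site selection, reference mapping.

#' Symmetric Kullback--Leibler information
#'
#' \eqn{D(p\|q) + D(q\|p)} between two compositions over the 20 amino acids
#' (or any pair of equal-length distributions). KL information alone is not
#' symmetric; the symmetrized sum is used to score between-group divergence.
#' Terms with \eqn{p_i = 0} contribute 0; a zero in one distribution facing
#' positive mass in the other makes the value infinite, which is an error
#' unless an epsilon floor is supplied (this can only arise with `beta = 0`).
#'
#' @param p,q non-negative vectors of equal length, each summing to 1.
#' @param log_base base of the logarithm (default `exp(1)`, nats).
#' @param epsilon optional floor applied to both vectors (then renormalized)
#'   to tolerate zeros.
#' @return Non-negative scalar; 0 iff `p == q`.
#' @export
symmetric_kl <- function(p, q, log_base = exp(1), epsilon = NULL) {
  if (length(p) != length(q)) stop("p and q differ in length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1")
  if (any(p < 0) || any(q < 0)) stop("negative mass in p or q")
  if (!is.null(epsilon)) {
    p <- pmax(p, epsilon); p <- p / sum(p)
    q <- pmax(q, epsilon); q <- q / sum(q)
  }
  if (any(p > 0 & q == 0) || any(q > 0 & p == 0))
    stop("infinite-divergence error: zero probability facing positive mass; ",
         "use a positive pseudocount weight or the epsilon floor")
  ip <- p > 0
  iq <- q > 0
  val <- sum(p[ip] * log(p[ip] / q[ip])) + sum(q[iq] * log(q[iq] / p[iq]))
  val / log(log_base)
}

#' Scoring parameters
#'
#' @param beta pseudocount weight (default 0.1).
#' @param gap_skip pooled gap fraction above which a column is skipped
#'   (default 0.5: more than half the sequences gapped).
#' @param log_base logarithm base for the KL value (default natural log).
#' @param model a `substitution_model`; the default (BLOSUM62 with
#'   Robinson--Robinson background) is built and solved on first use.
#' @param pooled_weights compute Henikoff weights on the pooled alignment and
#'   split them per group (default `FALSE`: per-group weights).
#' @return A list of class `klsite_params`.
#' @export
klsite_params <- function(beta = 0.1, gap_skip = 0.5, log_base = exp(1),
                          model = NULL, pooled_weights = FALSE) {
  structure(list(beta = beta, gap_skip = gap_skip, log_base = log_base,
                 model = model, pooled_weights = pooled_weights),
            class = "klsite_params")
}

#' Score every alignment column by symmetric KL information
#'
#' For each column: if the pooled gap fraction exceeds `gap_skip` the column
#' is skipped (`gap_majority`); if one group has no residues at the column it
#' is skipped (`group_empty`); otherwise the two groups' Henikoff-weighted,
#' pseudocount-regularized compositions are compared by [symmetric_kl()].
#' lambda_u is solved once per alignment from the model's background.
#'
#' @param aln a `grouped_alignment` with exactly two group labels.
#' @param params a [klsite_params()] list.
#' @return A `site_score_table` data.frame with columns `column`,
#'   `ref_residue` (NA until [select_top_sites()]), `kl_value`,
#'   `skip_reason` (`none`, `gap_majority`, `group_empty`) and `selected`.
#' @export
score_all_sites <- function(aln, params = klsite_params()) {
  if (is.null(aln$groups))
    stop("alignment has no group labels; call assign_groups() first")
  labs <- unique(aln$groups)
  if (length(labs) != 2L) stop("exactly two groups required")
  model <- params$model
  if (is.null(model)) model <- default_substitution_model()
  if (is.na(model$lambda_u)) model$lambda_u <- solve_lambda_u(model)

  E <- .encode_alignment(aln$matrix)
  ia <- which(aln$groups == labs[1L])
  ib <- which(aln$groups == labs[2L])
  EA <- E[ia, , drop = FALSE]
  EB <- E[ib, , drop = FALSE]
  if (all(EA == 0L) || all(EB == 0L))
    stop("a group is empty at every column")

  if (params$pooled_weights) {
    w <- henikoff_weights(E)
    wA <- w[ia] / sum(w[ia])
    wB <- w[ib] / sum(w[ib])
  } else {
    wA <- henikoff_weights(EA)
    wB <- henikoff_weights(EB)
  }

  L <- ncol(E)
  gapfrac <- colMeans(E == 0L)
  skip <- rep("none", L)
  skip[gapfrac > params$gap_skip] <- "gap_majority"

  FA <- .group_frequencies(EA, wA)
  FB <- .group_frequencies(EB, wB)
  emptyA <- colSums(FA) == 0
  emptyB <- colSums(FB) == 0
  skip[skip == "none" & (emptyA | emptyB)] <- "group_empty"

  ndA <- colSums(.letter_counts(EA) > 0L)
  ndB <- colSums(.letter_counts(EB) > 0L)
  QA <- .regularize_columns(FA, ndA, model, params$beta)
  QB <- .regularize_columns(FB, ndB, model, params$beta)

  kl <- rep(NA_real_, L)
  ev <- which(skip == "none")
  if (length(ev)) {
    A <- QA[, ev, drop = FALSE]
    B <- QB[, ev, drop = FALSE]
    # beta > 0 guarantees strictly positive compositions
    if (any(A == 0) || any(B == 0))
      stop("infinite-divergence error: zero regularized composition; ",
           "use beta > 0")
    kl[ev] <- (colSums(A * log(A / B)) + colSums(B * log(B / A))) /
      log(params$log_base)
  }
  structure(data.frame(column = seq_len(L), ref_residue = NA_integer_,
                       kl_value = kl, skip_reason = skip, selected = FALSE,
                       stringsAsFactors = FALSE),
            class = c("site_score_table", "data.frame"))
}

#' Select the top-quantile divergent sites
#'
#' Ranks evaluable columns by KL value (descending; ties broken by ascending
#' column index), marks the top `ceiling(quantile * n_evaluable)`, then
#' unmarks any marked column where the reference sequence is gapped (such
#' sites cannot be mapped onto the structure, so the final count may fall
#' below the ceiling). Reference residue numbers are attached for all mapped
#' columns.
#'
#' @param table a `site_score_table` from [score_all_sites()].
#' @param quantile selection fraction in (0, 1); default 0.05 (top 5%).
#' @param ref_map optional `reference_column_map` from
#'   [map_reference_columns()].
#' @return The table with `selected` flags and `ref_residue` filled in.
#' @export
select_top_sites <- function(table, quantile = 0.05, ref_map = NULL) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  ev <- which(table$skip_reason == "none")
  n_sel <- ceiling(quantile * length(ev))
  ord <- ev[order(-table$kl_value[ev], table$column[ev])]
  table$selected <- FALSE
  table$selected[ord[seq_len(min(n_sel, length(ord)))]] <- TRUE
  if (!is.null(ref_map)) {
    table$ref_residue <- NA_integer_
    cols <- as.integer(names(ref_map$column_to_residue))
    table$ref_residue[cols] <- ref_map$column_to_residue
    table$selected[table$column %in% ref_map$gapped_columns] <- FALSE
  }
  table
}

#' Write a per-site score table as TSV
#'
#' @param table a `site_score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
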