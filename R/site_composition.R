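# Site-specific amino acid composition of one group at one column:
# Henikoff-Henikoff position-based weights, weighted residue frequencies,
# and PSI-BLAST-style data-dependent pseudocount regularization.

# Encode a character alignment matrix as integers: 0 = gap, 1..20 = index
# into AA_ALPHABET20.
.encode_alignment <- function(mat) {
  E <- match(mat, AA_ALPHABET20, nomatch = 0L)
  dim(E) <- dim(mat)
  dimnames(E) <- dimnames(mat)
  E
}

# 20 x L matrix of per-column letter counts for an encoded matrix.
.letter_counts <- function(E) {
  vapply(seq_len(ncol(E)),
         function(c) tabulate(E[, c], nbins = 20L),
         integer(20L))
}

#' Henikoff--Henikoff position-based sequence weights
#'
#' At each column with `r` distinct non-gap residue types, a sequence showing
#' a type shared by `m` of the sequences receives increment `1/(r*m)`; gap
#' cells receive nothing. Per-sequence sums are normalized to total 1.
#' Sequences consisting entirely of gaps get weight 0 and the rest are
#' renormalized. The weights down-weight redundant (near-duplicate)
#' sequences so that an over-sampled subfamily does not dominate the
#' composition.
#'
#' @param rows character vector of equal-length aligned strings, or a
#'   character matrix (one row per sequence), or an encoded integer matrix.
#' @return Numeric weight vector summing to 1 (class `numeric`), one entry
#'   per sequence.
#' @export
henikoff_weights <- function(rows) {
  if (length(rows) == 0L) stop("empty group: no sequences")
  E <- .as_encoded(rows)
  if (is.null(dim(E)) || nrow(E) == 0L) stop("empty group: no sequences")
  C <- .letter_counts(E)                      # 20 x L counts
  r <- colSums(C > 0L)                        # distinct types per column
  inc <- matrix(0, nrow(E), ncol(E))
  idx <- which(E > 0L)
  if (length(idx)) {
    cc <- ((idx - 1L) %/% nrow(E)) + 1L       # column of each non-gap cell
    m <- C[cbind(E[idx], cc)]
    inc[idx] <- 1 / (r[cc] * m)
  }
  w <- rowSums(inc)
  if (sum(w) == 0) stop("empty group: all sequences are entirely gaps")
  w / sum(w)
}

.as_encoded <- function(rows) {
  if (is.matrix(rows) && is.numeric(rows)) return(rows)
  if (is.character(rows) && !is.matrix(rows)) {
    rows <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  }
  rows[rows %in% .AMBIGUITY_CODES] <- "-"
  .encode_alignment(rows)
}

#' Weighted residue frequencies at one column
#'
#' @param letters character vector, one letter (or `-`) per sequence.
#' @param w weight vector from [henikoff_weights()] (same length).
#' @return List with `f` (20-vector summing to 1 over the non-gap mass,
#'   named by amino acid), `n_distinct` (distinct residue types present) and
#'   `empty` (TRUE when every sequence is gapped at the column).
#' @export
weighted_frequencies <- function(letters, w) {
  if (length(letters) != length(w)) stop("letters and weights differ in length")
  e <- match(toupper(letters), AA_ALPHABET20, nomatch = 0L)
  f <- stats::setNames(numeric(20L), AA_ALPHABET20)
  keep <- e > 0L
  if (!any(keep))
    return(list(f = f, n_distinct = 0L, empty = TRUE))
  tot <- vapply(seq_len(20L), function(i) sum(w[keep][e[keep] == i]), 0)
  f[] <- tot / sum(tot)
  list(f = f, n_distinct = length(unique(e[keep])), empty = FALSE)
}

#' Pseudocount-regularized composition
#'
#' PSI-BLAST's data-dependent pseudocount: with target frequencies
#' \eqn{q_{ij} = P_i P_j e^{\lambda_u s_{ij}}}, the pseudocount vector is
#' \eqn{g_i = \sum_j (f_j / P_j) q_{ij}} and the regularized composition is
#' \eqn{(\alpha f + \beta g) / (\alpha + \beta)} with
#' \eqn{\alpha = n_{distinct} - 1}. A single-residue column
#' (\eqn{\alpha = 0}) returns `g` renormalized. The result is renormalized
#' to sum exactly to 1 and is strictly positive whenever `beta > 0`.
#'
#' @param f 20-vector of observed weighted frequencies (sums to 1).
#' @param n_distinct distinct residue types observed at the column.
#' @param model a solved `substitution_model`.
#' @param beta pseudocount weight (default 0.1).
#' @return 20-vector `q_reg`, named by amino acid.
#' @export
pseudocount_composition <- function(f, n_distinct, model, beta = 0.1) {
  if (beta < 0) stop("beta must be >= 0")
  if (is.na(model$lambda_u)) stop("model lambda_u is unsolved")
  if (abs(sum(f) - 1) > 1e-6) stop("f must sum to 1")
  alpha <- max(n_distinct - 1, 0)
  if (alpha + beta == 0) return(f / sum(f))
  M <- exp(model$lambda_u * model$scores)
  g <- model$background * drop(M %*% f)      # g_i = sum_j f_j P_i e^{lambda s_ij}
  q <- alpha * f + beta * g
  q <- q / sum(q)
  names(q) <- if (length(q) == 20L) AA_ALPHABET20 else names(f)
  q
}

# Vectorized internals used by score_all_sites ------------------------------

# 20 x L weighted frequency matrix for an encoded group matrix; columns with
# no non-gap mass are all-zero.
.group_frequencies <- function(E, w) {
  F <- matrix(0, 20L, ncol(E))
  for (i in seq_len(20L)) F[i, ] <- colSums(w * (E == i))
  s <- colSums(F)
  ok <- s > 0
  F[, ok] <- sweep(F[, ok, drop = FALSE], 2L, s[ok], "/")
  F
}

# Column-wise pseudocount regularization of a 20 x L frequency matrix.
.regularize_columns <- function(F, n_distinct, model, beta) {
  alpha <- pmax(n_distinct - 1, 0)
  M <- exp(model$lambda_u * model$scores)
  G <- model$background * (M %*% F)
  Q <- sweep(F, 2L, alpha, "*") + beta * G
  s <- colSums(Q)
  ok <- s > 0
  Q[, ok] <- sweep(Q[, ok, drop = FALSE], 2L, s[ok], "/")
  zero <- which(!ok & colSums(F) > 0)        # alpha + beta == 0: keep f
  if (length(zero)) Q[, zero] <- F[, zero]
  Q
}
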