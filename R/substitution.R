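# Substitution model: score matrix, background frequencies, and the ungapped
# scale parameter lambda_u relating scores to target frequencies.

# Robinson & Robinson (1991) amino acid background frequencies, the standard
# PSI-BLAST background. Order follows AA_ALPHABET20.
.ROBINSON_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Construct a substitution model
#'
#' Bundles a symmetric 20x20 score matrix with background frequencies and
#' (optionally) the ungapped scale lambda_u satisfying
#' \eqn{\sum_{ij} P_i P_j e^{\lambda s_{ij}} = 1}. The scale converts scores
#' into the target (joint substitution) frequencies
#' \eqn{q_{ij} = P_i P_j e^{\lambda s_{ij}}} used by the pseudocount profile.
#'
#' @param scores 20x20 numeric matrix with row/column names covering the 20
#'   standard amino acids (extra rows such as B/Z/X are dropped).
#' @param background positive 20-vector of background frequencies, named by
#'   amino acid; renormalized to sum to 1. Defaults to the Robinson--Robinson
#'   frequencies.
#' @param lambda optional pre-computed positive scale; solved on demand by
#'   [solve_lambda_u()] when `NULL`.
#' @return An object of class `substitution_model` with elements `scores`,
#'   `background`, `lambda_u` (possibly `NA`).
#' @export
substitution_model <- function(scores,
                               background = .ROBINSON_BACKGROUND,
                               lambda = NULL) {
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score matrix must have amino acid row and column names")
  miss <- setdiff(AA_ALPHABET20, rownames(scores))
  if (length(miss))
    stop("score matrix missing rows: ", paste(miss, collapse = ", "))
  S <- scores[AA_ALPHABET20, AA_ALPHABET20]
  if (max(abs(S - t(S))) > 1e-9) stop("score matrix is not symmetric")
  P <- background[AA_ALPHABET20]
  if (anyNA(P) || any(P <= 0))
    stop("background must be positive for all 20 amino acids")
  P <- P / sum(P)
  structure(list(scores = S, background = P,
                 lambda_u = if (is.null(lambda)) NA_real_ else lambda),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution_model: 20x20 scores, lambda_u = %s\n",
              if (is.na(x$lambda_u)) "<unsolved>"
              else format(x$lambda_u, digits = 6)))
  invisible(x)
}

#' Default substitution model (BLOSUM62, Robinson--Robinson background)
#'
#' The PSI-BLAST defaults: BLOSUM62 scores with Robinson--Robinson background
#' frequencies, lambda_u solved at construction (approximately 0.3176).
#'
#' @return A solved `substitution_model`.
#' @export
default_substitution_model <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- substitution_model(env$BLOSUM62)
  m$lambda_u <- solve_lambda_u(m)
  m
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix format used by BLAST (`#` comments, a header
#' row of letters, one labelled row per letter). Rows and columns outside the
#' 20 standard amino acids are dropped.
#'
#' @param path path to the matrix file.
#' @param background,lambda passed to [substitution_model()].
#' @return A `substitution_model`.
#' @export
read_substitution_matrix <- function(path,
                                     background = .ROBINSON_BACKGROUND,
                                     lambda = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  labs <- vapply(body, `[`, "", 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(labs, header)
  keep <- intersect(labs, AA_ALPHABET20)
  substitution_model(vals[keep, keep], background, lambda)
}

#' Solve the ungapped scale lambda_u
#'
#' Finds the unique positive root of
#' \eqn{g(\lambda) = \sum_{ij} P_i P_j e^{\lambda s_{ij}} - 1} by
#' Newton--Raphson with a maintained bracket and bisection fallback. The root
#' exists and is unique when the expected score under the background is
#' negative and at least one score is positive (g is convex, g(0)=0,
#' g'(0)<0, g to +Inf).
#'
#' @param model a `substitution_model`.
#' @param tol convergence tolerance on `|g(lambda)|`.
#' @param max_iter iteration cap.
#' @return The positive root (numeric scalar).
#' @export
solve_lambda_u <- function(model, tol = 1e-12, max_iter = 200L) {
  S <- model$scores
  P <- model$background
  PP <- outer(P, P)
  g  <- function(l) sum(PP * exp(l * S)) - 1
  dg <- function(l) sum(PP * S * exp(l * S))
  if (sum(PP * S) >= 0)
    stop("no-positive-root error: expected score under background is >= 0")
  if (max(S) <= 0)
    stop("no-positive-root error: all scores non-positive, g(lambda) < 0 for lambda > 0")
  # bracket: g < 0 just right of 0, g > 0 at hi
  lo <- .Machine$double.eps
  hi <- 0.25
  while (g(hi) <= 0) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e4) stop("numerical error: failed to bracket positive root")
  }
  lambda <- hi
  for (it in seq_len(max_iter)) {
    gl <- g(lambda)
    if (abs(gl) <= tol) return(lambda)
    if (gl > 0) hi <- lambda else lo <- lambda
    step <- gl / dg(lambda)
    cand <- lambda - step
    # keep the iterate inside the bracket; bisect otherwise
    if (!is.finite(cand) || cand <= lo || cand >= hi) cand <- (lo + hi) / 2
    if (abs(cand - lambda) < .Machine$double.eps * max(1, lambda) &&
        abs(gl) <= 1e-9)
      return(lambda)
    lambda <- cand
  }
  if (abs(g(lambda)) <= 1e-9) return(lambda)
  stop("numerical error: lambda solver did not converge in ", max_iter,
       " iterations")
}
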