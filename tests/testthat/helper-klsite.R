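# Shared fixtures and independent oracles for the test suite.

# Two-letter toy substitution model: P = (1/2, 1/2), s = [[1, -2], [-2, 1]].
# The lambda constraint sum P_i P_j e^{lambda s_ij} = 1 reduces (with
# x = e^lambda) to x^3 - 2x^2 + 1 = 0, whose relevant root is the golden
# ratio, so lambda = log((1 + sqrt(5)) / 2).
toy_model2 <- function(lambda = NULL) {
  s <- matrix(c(1, -2, -2, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  structure(list(scores = s, background = c(a = 0.5, b = 0.5),
                 lambda_u = if (is.null(lambda)) NA_real_ else lambda),
            class = "substitution_model")
}

TOY_LAMBDA <- log((1 + sqrt(5)) / 2)

# Solved default model, built once for the whole suite.
TEST_MODEL <- default_substitution_model()
TEST_PARAMS <- klsite_params(model = TEST_MODEL)

# Independent Welch t-test oracle: the textbook formulae, written without
# reference to stats::t.test.
welch_oracle <- function(x, y, alternative = "two_sided") {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- switch(alternative,
              two_sided = 2 * stats::pt(-abs(t), df),
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE))
  list(t = t, df = df, p = p)
}

# A minimal hand-written PDB fixture with three CA atoms on chain A.
write_mini_pdb <- function(path, extra_lines = character(0)) {
  lines <- c(
    "HEADER    TEST STRUCTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       7.000   8.000   9.000  1.00  0.00           C",
    "HETATM    5  O   HOH A 101      -1.000  -1.000  -1.000  1.00  0.00           O",
    extra_lines,
    "END")
  writeLines(lines, path)
  path
}

# Hand-built structure model (bypassing PDB parsing) for geometry tests.
manual_structure <- function(resno, xyz) {
  rownames(xyz) <- resno
  structure(list(resno = as.integer(resno), xyz = xyz, chain = "A"),
            class = "structure_model")
}

# A random proper rotation matrix (QR-based, determinant +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
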