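test_that("symmetric KL is zero at equality, symmetric, and matches the
           two-letter hand value", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(symmetric_kl(p, p), 0)

  # each direction contributes 0.5 * log 3
  p2 <- c(0.75, 0.25); q2 <- c(0.25, 0.75)
  expect_equal(symmetric_kl(p2, q2), log(3), tolerance = 1e-12)
  expect_identical(symmetric_kl(p2, q2), symmetric_kl(q2, p2))
  expect_equal(symmetric_kl(p2, q2, log_base = 2), log2(3),
               tolerance = 1e-12)

  set.seed(3)
  for (i in 1:20) {
    a <- stats::rgamma(20, 0.5); a <- a / sum(a)
    b <- stats::rgamma(20, 0.5); b <- b / sum(b)
    v <- symmetric_kl(a, b)
    expect_gte(v, 0)
    expect_equal(v, symmetric_kl(b, a))
  }
})

test_that("zeros facing positive mass error out unless the epsilon floor is
           used", {
  p <- c(1, 0); q <- c(0.5, 0.5)
  expect_error(symmetric_kl(p, q), "infinite-divergence")
  v <- symmetric_kl(p, q, epsilon = 1e-6)
  expect_true(is.finite(v) && v > 0)
  expect_error(symmetric_kl(c(0.4, 0.6), c(0.7, 0.4)), "sum to 1")
})

test_that("score_all_sites skips gap-majority columns and scores planted
           divergence above background", {
  gen <- generate_alignment(n_a = 30, n_b = 30, n_columns = 60,
                            planted_sites = c(10, 25, 40), divergence = 1,
                            gap_rate = 0, majority_gap_sites = c(3, 50),
                            seed = 5)
  tab <- score_all_sites(gen$alignment, TEST_PARAMS)
  expect_s3_class(tab, "site_score_table")
  expect_equal(tab$column, 1:60)
  expect_equal(which(tab$skip_reason == "gap_majority"), c(3L, 50L))
  expect_true(all(is.na(tab$kl_value[tab$skip_reason != "none"])))
  expect_true(all(is.finite(tab$kl_value[tab$skip_reason == "none"])))
  expect_true(all(tab$kl_value[tab$skip_reason == "none"] >= 0))
  # full divergence: every planted column outscores every unplanted one
  planted_kl <- tab$kl_value[gen$truth]
  other_kl <- tab$kl_value[setdiff(which(tab$skip_reason == "none"),
                                   gen$truth)]
  expect_gt(min(planted_kl), max(other_kl))
})

test_that("identical groups give (near-)zero KL at every column", {
  rows <- c("ACDEF", "ACDEW", "ACDEF", "ACDEW")
  aln <- grouped_alignment(paste0("s", 1:4), rows,
                           groups = stats::setNames(c("x", "x", "y", "y"),
                                                    paste0("s", 1:4)))
  tab <- score_all_sites(aln, TEST_PARAMS)
  # groups have identical rows, hence identical f and n_distinct
  expect_equal(tab$kl_value, rep(0, 5), tolerance = 1e-12)
})

test_that("a column left empty in one group is skipped, not scored", {
  rows <- c("AC", "AC", "AC", "A-", "A-", "A-")
  g <- stats::setNames(rep(c("x", "y"), each = 3), paste0("s", 1:6))
  aln <- grouped_alignment(paste0("s", 1:6), rows, groups = g)
  tab <- score_all_sites(aln, TEST_PARAMS)
  expect_equal(tab$skip_reason, c("none", "group_empty"))
})

test_that("top-quantile selection takes the ceiling, breaks ties by column,
           then drops reference-gapped sites", {
  mk_table <- function(kl) {
    structure(data.frame(column = seq_along(kl), ref_residue = NA_integer_,
                         kl_value = kl, skip_reason = "none",
                         selected = FALSE),
              class = c("site_score_table", "data.frame"))
  }
  set.seed(8)
  kl <- sample(seq(0.01, 1, length.out = 100))
  tab <- select_top_sites(mk_table(kl), 0.05)
  expect_equal(sum(tab$selected), 5L)
  expect_setequal(which(tab$selected), order(-kl)[1:5])

  # two of the top five fall in reference-gap columns -> only three survive
  ref_map <- structure(list(
    column_to_residue = stats::setNames(
      seq_len(98), setdiff(1:100, order(-kl)[1:2])),
    gapped_columns = order(-kl)[1:2]), class = "reference_column_map")
  tab2 <- select_top_sites(mk_table(kl), 0.05, ref_map)
  expect_equal(sum(tab2$selected), 3L)
  expect_setequal(which(tab2$selected), order(-kl)[3:5])
  expect_true(all(!is.na(tab2$ref_residue[tab2$selected])))

  # tiny quantile: single argmax
  tab3 <- select_top_sites(mk_table(kl), 1e-6)
  expect_equal(which(tab3$selected), which.max(kl))

  # ties at the cutoff resolve to the smallest column indices
  tied <- mk_table(c(5, 5, 5, 5, 1, 1, 1, 1, 1, 1))
  tab4 <- select_top_sites(tied, 0.2)
  expect_equal(which(tab4$selected), c(1L, 2L))

  # selection is rank-based: any monotone rescaling picks the same sites
  tab5 <- select_top_sites(mk_table(exp(3 * kl)), 0.05)
  expect_equal(which(tab5$selected), which(tab$selected))

  expect_error(select_top_sites(mk_table(kl), 0), "quantile")
})

test_that("selection count never exceeds the quantile ceiling of evaluable
           columns", {
  gen <- generate_alignment(n_a = 12, n_b = 12, n_columns = 80,
                            planted_sites = c(5, 15), divergence = 0.7,
                            gap_rate = 0.1, majority_gap_sites = c(2, 70),
                            seed = 13)
  tab <- score_all_sites(gen$alignment, TEST_PARAMS)
  ref_map <- map_reference_columns(gen$alignment)
  for (q in c(0.02, 0.05, 0.2)) {
    sel <- select_top_sites(tab, q, ref_map)
    n_eval <- sum(sel$skip_reason == "none")
    expect_lte(sum(sel$selected), ceiling(q * n_eval))
  }
})

test_that("site tables write as TSV with a header", {
  gen <- generate_alignment(n_a = 5, n_b = 5, n_columns = 10, seed = 2)
  tab <- score_all_sites(gen$alignment, TEST_PARAMS)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 10L)
  expect_named(back, c("column", "ref_residue", "kl_value", "skip_reason",
                       "selected"))
})
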