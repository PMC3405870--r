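test_that("PDB Calpha extraction keeps one atom per residue and ignores
           HETATM", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(path)
  m <- read_structure(path, "A")
  expect_equal(m$resno, 1:3)
  expect_equal(unname(m$xyz[1, ]), c(1, 2, 3))
  expect_equal(unname(m$xyz[3, ]), c(7, 8, 9))
  expect_error(read_structure(path, "Z"), "chain 'Z' not found")
})

test_that("first altloc wins and insertion codes are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(path, extra_lines = c(
    "ATOM      6  CA ALEU A   4      10.000  10.000  10.000  0.50  0.00           C",
    "ATOM      7  CA BLEU A   4      20.000  20.000  20.000  0.50  0.00           C"))
  m <- read_structure(path, "A")
  expect_equal(unname(m$xyz["4", ]), c(10, 10, 10))

  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00  0.00           C",
    "END"), path2)
  expect_error(read_structure(path2, "A"), "insertion codes")
})

test_that("axis construction: symmetric toy, translation equivariance,
           degenerate errors", {
  cfg <- region_config(data.frame(label = c("N", "ICL1"),
                                  start = c(1, 5), end = c(4, 8)))
  xyz <- rbind(matrix(rep(c(0, 0, 10), each = 4), 4),
               matrix(rep(c(0, 0, -10), each = 4), 4))
  m <- manual_structure(1:8, xyz)
  ax <- compute_axis(m, cfg)
  expect_equal(unname(ax$midpoint), c(0, 0, 0))
  expect_equal(unname(ax$unit_vector), c(0, 0, 1))
  expect_equal(sqrt(sum(ax$unit_vector^2)), 1, tolerance = 1e-12)
  expect_gt(sum(ax$unit_vector * (ax$center_extra - ax$midpoint)), 0)

  m2 <- manual_structure(1:8, sweep(xyz, 2, c(-5, -5, -5)))
  ax2 <- compute_axis(m2, cfg)
  expect_equal(unname(ax2$midpoint), c(5, 5, 5))
  expect_equal(unname(ax2$unit_vector), c(0, 0, 1))

  # coincident centers
  m3 <- manual_structure(1:8, matrix(1, 8, 3))
  expect_error(compute_axis(m3, cfg), "degenerate-axis")
  # empty region set
  cfg_bad <- region_config(data.frame(label = c("N", "ICL1"),
                                      start = c(100, 5), end = c(101, 8)))
  expect_error(compute_axis(m, cfg_bad), "extracellular")
})

test_that("projection is the signed inner product along the axis", {
  cfg <- region_config(data.frame(label = c("ECL1", "ICL1"),
                                  start = c(1, 3), end = c(2, 4)))
  m <- manual_structure(1:6, rbind(c(0, 0, 10), c(0, 0, 10),
                                   c(0, 0, -10), c(0, 0, -10),
                                   c(0, 0, 4), c(3, 4, -2)))
  ax <- compute_axis(m, cfg)
  pr <- project_residues(m, ax, cfg)
  expect_equal(pr$score[pr$residue == 5], 4)
  # lateral offsets are discarded by the projection
  expect_equal(pr$score[pr$residue == 6], -2)
  # a residue at the midpoint scores zero
  m$xyz["5", ] <- ax$midpoint
  expect_equal(project_residues(m, ax, cfg)$score[5], 0)
})

test_that("C-terminal residues are projected but excluded ranges are not", {
  st <- generate_structure()
  proj <- project_residues(st$model, compute_axis(st$model, st$config),
                           st$config)
  expect_true(any(proj$region == "C"))

  cfg2 <- st$config
  cterm <- cfg2$ranges[cfg2$ranges$label == "C", ]
  cfg2$excluded_ranges <- data.frame(start = cterm$start, end = cterm$end)
  proj2 <- project_residues(st$model, compute_axis(st$model, cfg2), cfg2)
  expect_false(any(proj2$region == "C"))
  expect_false(any(proj2$residue %in% cterm$start:cterm$end))
})

test_that("loop residues fall on their own membrane side and the axis scores
           split the inter-center distance evenly", {
  st <- generate_structure(seed = 4)
  ax <- compute_axis(st$model, st$config)
  proj <- project_residues(st$model, ax, st$config)
  expect_true(all(proj$score[grepl("^ECL", proj$region)] > 0))
  expect_true(all(proj$score[grepl("^ICL", proj$region)] < 0))
  expect_gt(mean(proj$score[proj$region == "N"]), 0)
  expect_lt(mean(proj$score[proj$region == "C"]), 0)

  half <- sqrt(sum((ax$center_extra - ax$center_intra)^2)) / 2
  expect_equal(sum(ax$unit_vector * (ax$center_extra - ax$midpoint)), half)
  expect_equal(sum(ax$unit_vector * (ax$center_intra - ax$midpoint)), -half)
})

test_that("projection scores are rigid-body invariant", {
  st <- generate_structure(jitter = 0.3, seed = 9)
  ax <- compute_axis(st$model, st$config)
  p0 <- project_residues(st$model, ax, st$config)

  set.seed(17)
  R <- random_rotation()
  tr <- c(12, -7, 30)
  st2 <- st
  st2$model$xyz <- sweep(st$model$xyz %*% t(R), 2, -tr)
  p1 <- project_residues(st2$model, compute_axis(st2$model, st$config),
                         st$config)
  expect_equal(p1$score, p0$score, tolerance = 1e-9)
})

test_that("tm_center_distance reflects bundle displacement along the axis", {
  st <- generate_structure(n_nterm = 0, n_cterm = 0,
                           loop_layout = "balanced")
  ax <- compute_axis(st$model, st$config)
  expect_lt(tm_center_distance(st$model, ax, st$config), 1e-9)

  # shift only the TM residues one Angstrom up the axis
  st2 <- st
  lab <- region_of(st$model$resno, st$config)
  tm <- grepl("^TM", lab)
  st2$model$xyz[tm, 3] <- st2$model$xyz[tm, 3] + 1
  expect_equal(tm_center_distance(st2$model, compute_axis(st2$model,
                                                          st$config),
                                  st$config), 1.0, tolerance = 1e-9)

  cfg_no_tm <- region_config(data.frame(label = c("ECL1", "ICL1"),
                                        start = c(1, 2), end = c(1, 2)))
  expect_error(tm_center_distance(st$model, ax, cfg_no_tm), "no TM residues")
})

test_that("projection results write as TSV with a header", {
  st <- generate_structure(n_loop = 3, n_tm = 8)
  proj <- project_residues(st$model, compute_axis(st$model, st$config),
                           st$config)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_projection_table(proj, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(proj))
  expect_named(back, c("residue", "region", "score", "selected"))
})

test_that("the packaged CXCR4 region config parses and covers the receptor", {
  cfg <- read_region_config(cxcr4_region_config_path(),
                            cxcr4_pocket_residues_path())
  expect_setequal(setdiff(cfg$ranges$label, "EXCLUDE"),
                  c("N", paste0("TM", 1:7), paste0("ECL", 1:3),
                    paste0("ICL", 1:3), "C"))
  expect_equal(cfg$cterm_range, c(303, 328))
  expect_equal(nrow(cfg$excluded_ranges), 1L)
  expect_true(all(diff(cfg$ranges$start) > 0))
  # contiguous coverage from the N-terminus into the C-tail
  expect_equal(cfg$ranges$start[-1], cfg$ranges$end[-nrow(cfg$ranges)] + 1)
  expect_gt(length(cfg$pocket_residues), 10)
  expect_equal(region_of(c(134, 252, 30, 1100), cfg),
               c("ICL2", "TM6", "N", "excluded"))
})
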