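# Generators for synthetic inputs with the statistical structure the
# analysis assumes: two-group alignments with planted divergent columns, and
# parametric toy helical-bundle structures with labelled loop regions.

# Residue set toward which planted divergence moves probability mass.
# Disjoint from the planted columns' shared support, so the between-group
# KL grows monotonically with the divergence parameter.
.PLANT_TARGET <- c("K", "R", "E", "D")

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  while (sum(x) == 0) x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Generate a two-group alignment with planted divergent columns
#'
#' Every column draws one shared composition from a symmetric Dirichlet over
#' the 20 amino acids. At planted columns the groups' compositions move
#' apart with the divergence parameter `d`:
#' group A uses `(1 - d) * shared + d * restrict(shared)` (the shared
#' composition with its `{K,R,E,D}` mass removed and renormalized) and
#' group B uses `(1 - d) * shared + d * uniform{K,R,E,D}`. At `d = 0`
#' planted columns are statistically identical to unplanted ones (chance
#' recall); at `d = 1` the two compositions have disjoint supports, so the
#' between-group KL grows with `d`. Letters are sampled i.i.d. per cell;
#' gaps are injected per
#' cell at `gap_rate`, except in the reference sequence (the first group-A
#' sequence, modelling the complete structure-bearing sequence).
#' `majority_gap_sites` columns are forced above the half-gapped threshold
#' by gapping `floor(n/2) + 1` non-reference rows.
#'
#' @param n_a,n_b sequences per group (defaults 40/40).
#' @param n_columns alignment length (default 300).
#' @param planted_sites integer vector of planted column indices (1-based).
#' @param divergence separation parameter in `[0, 1]` (default 0.9).
#' @param background_concentration symmetric Dirichlet concentration for
#'   per-column compositions (default 0.5; small values give the
#'   low-entropy, few-residue columns typical of protein families).
#' @param gap_rate per-cell gap probability (default 0.05).
#' @param majority_gap_sites columns forced above the gap-skip threshold.
#' @param seed optional integer seed; when `NULL` (default) the current RNG
#'   state is used, so reproducibility is controlled by the caller's
#'   `set.seed()`. Given a seed, generation is bit-reproducible.
#' @return List with `alignment` (a `grouped_alignment`, groups `"A"`/`"B"`,
#'   reference `"A_1"`) and `truth` (sorted integer vector of planted
#'   columns).
#' @export
generate_alignment <- function(n_a = 40L, n_b = 40L, n_columns = 300L,
                               planted_sites = integer(0), divergence = 0.9,
                               background_concentration = 0.5,
                               gap_rate = 0.05,
                               majority_gap_sites = integer(0),
                               seed = NULL) {
  if (any(planted_sites < 1L | planted_sites > n_columns))
    stop("planted_sites outside 1..n_columns")
  if (length(intersect(planted_sites, majority_gap_sites)))
    stop("spec error: a planted site cannot also be a majority-gap site ",
         "(it would be undetectable by construction)")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_a + n_b
  plant_idx <- match(.PLANT_TARGET, AA_ALPHABET20)
  target <- numeric(20L)
  target[plant_idx] <- 1 / length(plant_idx)

  mat <- matrix("-", n, n_columns)
  for (col in seq_len(n_columns)) {
    shared <- .rdirichlet1(rep(background_concentration, 20L))
    if (col %in% planted_sites && divergence > 0) {
      away <- shared
      away[plant_idx] <- 0
      away <- away / sum(away)               # a.s. well-defined
      pA <- (1 - divergence) * shared + divergence * away
      pB <- (1 - divergence) * shared + divergence * target
    } else {
      pA <- shared
      pB <- shared
    }
    mat[seq_len(n_a), col] <- sample(AA_ALPHABET20, n_a, TRUE, pA)
    mat[n_a + seq_len(n_b), col] <- sample(AA_ALPHABET20, n_b, TRUE, pB)
  }
  if (gap_rate > 0) {
    gaps <- matrix(stats::runif(n * n_columns) < gap_rate, n, n_columns)
    gaps[1L, ] <- FALSE                       # reference stays complete
    mat[gaps] <- "-"
  }
  for (col in majority_gap_sites) {
    k <- floor(n / 2) + 1L
    mat[sample(2:n, k), col] <- "-"
  }
  ids <- c(paste0("A_", seq_len(n_a)), paste0("B_", seq_len(n_b)))
  groups <- stats::setNames(rep(c("A", "B"), c(n_a, n_b)), ids)
  list(alignment = grouped_alignment(ids, mat, groups = groups,
                                     reference_id = "A_1"),
       truth = sort(as.integer(planted_sites)))
}

#' Generate a toy seven-helix bundle structure
#'
#' Builds an idealized GPCR-like Calpha trace: seven vertical helices on a
#' circle, spanning `z` in `[-z_half, +z_half]` with alternating direction,
#' loops placed beyond the membrane boundaries in the canonical topology
#' (N-terminus extracellular, then ICL1, ECL1, ICL2, ECL2, ICL3, ECL3,
#' C-terminus intracellular). All ECL/N residues have `z > 0` and all ICL/C
#' residues `z < 0`. Residues are numbered consecutively in chain order.
#'
#' @param n_tm residues per helix (default 24).
#' @param n_loop residues per loop (default 6).
#' @param n_nterm,n_cterm terminal segment lengths (defaults 10 and 12; set
#'   both to 0 for an exactly mirror-symmetric bundle).
#' @param radius bundle radius in Angstrom (default 11).
#' @param rise helix rise per residue in Angstrom (default 1.5).
#' @param loop_bulge how far beyond the helix ends loops sit (default 3).
#' @param loop_layout `"adjacent"` (default) places each loop between the
#'   two helices it connects, as in a real receptor; `"balanced"` places the
#'   three loops of each side 120 degrees apart with the same angular
#'   offsets on both sides, making the extracellular and intracellular loop
#'   sets exact mirror images through the membrane midplane (so, with both
#'   terminal arms empty, the axis midpoint coincides with the TM-bundle
#'   center to machine precision).
#' @param jitter s.d. of isotropic coordinate noise in Angstrom (default 0).
#' @param seed optional integer seed (relevant only when `jitter > 0`); when
#'   `NULL` the current RNG state is used.
#' @return List with `model` (a `structure_model`) and `config` (a matching
#'   `region_config`).
#' @export
generate_structure <- function(n_tm = 24L, n_loop = 6L, n_nterm = 10L,
                               n_cterm = 12L, radius = 11, rise = 1.5,
                               loop_bulge = 3,
                               loop_layout = c("adjacent", "balanced"),
                               jitter = 0, seed = NULL) {
  loop_layout <- match.arg(loop_layout)
  if (!is.null(seed)) set.seed(as.integer(seed))
  z_half <- (n_tm - 1) * rise / 2
  helix_angle <- function(k) 2 * pi * (k - 1) / 7
  # local helix spiral, centered to zero mean so the TM centroid is exact
  phi <- 100 * pi / 180 * (seq_len(n_tm) - 1)
  sx <- 2.3 * cos(phi); sx <- sx - mean(sx)
  sy <- 2.3 * sin(phi); sy <- sy - mean(sy)
  helix_coords <- function(k, i, down) {
    th <- helix_angle(k)
    z <- if (down) z_half - (i - 1) * rise else -z_half + (i - 1) * rise
    c(radius * cos(th) + sx[i], radius * sin(th) + sy[i], z)
  }
  loop_coords <- function(th_from, th_to, i, n, top) {
    # arc between two bundle angles, pushed past the membrane boundary
    t <- i / (n + 1)
    th <- (1 - t) * th_from + t * th_to
    z <- (if (top) 1 else -1) * (z_half + loop_bulge * sin(pi * t) + 1)
    c(radius * cos(th), radius * sin(th), z)
  }
  loop_angles <- function(k, idx_on_side) {
    if (loop_layout == "adjacent") {
      c(helix_angle(k), helix_angle(k + 1))
    } else {
      mid <- 2 * pi * (idx_on_side - 1) / 3
      mid + c(-1, 1) * pi / 7
    }
  }
  segs <- list()
  add <- function(label, coords) {
    if (!is.null(coords) && nrow(coords))
      segs[[length(segs) + 1L]] <<- list(label = label, coords = coords)
  }
  seg_coords <- function(n, f) if (n == 0L) NULL else
    t(vapply(seq_len(n), f, numeric(3L)))
  add("N", seg_coords(n_nterm, function(i)
    loop_coords(helix_angle(1), helix_angle(1), i, n_nterm, top = TRUE) +
      c(0, 0, i * 0.8)))
  down <- TRUE
  for (k in 1:7) {
    add(paste0("TM", k), seg_coords(n_tm, function(i)
      helix_coords(k, i, down)))
    if (k < 7) {
      idx <- if (down) (k + 1) %/% 2 else k %/% 2
      loop_lab <- paste0(if (down) "ICL" else "ECL", idx)
      th <- loop_angles(k, idx)
      add(loop_lab, seg_coords(n_loop, function(i)
        loop_coords(th[1L], th[2L], i, n_loop, top = !down)))
    }
    down <- !down
  }
  add("C", seg_coords(n_cterm, function(i)
    loop_coords(helix_angle(7), helix_angle(7), i, n_cterm, top = FALSE) -
      c(0, 0, i * 0.8)))

  xyz <- do.call(rbind, lapply(segs, `[[`, "coords"))
  if (jitter > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter),
                                      nrow(xyz))
  nres <- nrow(xyz)
  resno <- seq_len(nres)
  dimnames(xyz) <- list(resno, c("x", "y", "z"))
  lens <- vapply(segs, function(s) nrow(s$coords), 0L)
  labels <- vapply(segs, `[[`, "", "label")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  cfg <- region_config(data.frame(label = labels, start = starts, end = ends,
                                  stringsAsFactors = FALSE))
  model <- structure(list(resno = as.integer(resno), xyz = xyz, chain = "A"),
                     class = "structure_model")
  list(model = model, config = cfg)
}

#' Write a structure model as a minimal PDB file
#'
#' One fixed-width `ATOM` Calpha record per residue (residue name `ALA`,
#' chain `A`), readable by [read_structure()] and standard PDB tools.
#' Coordinates are stored at the format's 0.001 Angstrom precision.
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(model$resno), model$chain, model$resno,
    model$xyz[, 1L], model$xyz[, 2L], model$xyz[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a region config as TSV
#'
#' @param cfg a `region_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_config <- function(cfg, path) {
  tab <- cfg$ranges[, c("label", "start", "end")]
  if (nrow(cfg$excluded_ranges))
    tab <- rbind(tab, data.frame(label = "EXCLUDE", cfg$excluded_ranges))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Precision and recall of planted-site recovery
#'
#' @param selected integer vector of selected column indices.
#' @param planted integer vector of planted (truth) column indices.
#' @return List with `precision` (`NA` when nothing is selected), `recall`,
#'   and `n_overlap`.
#' @export
evaluate_recovery <- function(selected, planted) {
  ov <- length(intersect(selected, planted))
  list(precision = if (length(selected)) ov / length(selected) else NA_real_,
       recall = if (length(planted)) ov / length(planted) else NA_real_,
       n_overlap = ov)
}
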