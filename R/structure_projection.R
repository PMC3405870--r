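# Reference structure handling: Calpha extraction, topological region labels,
# the extracellular<->intracellular axis, and per-residue projections.

.REGION_LABELS <- c("N", paste0("TM", 1:7), paste0("ECL", 1:3),
                    paste0("ICL", 1:3), "C")

#' Read a region-definition config
#'
#' Tab- or whitespace-delimited text with a header `label start end`. Labels
#' are `N`, `TM1`..`TM7`, `ECL1`..`ECL3`, `ICL1`..`ICL3`, `C` (residue-number
#' intervals, inclusive) plus optional `EXCLUDE` rows for ranges dropped
#' entirely (e.g. a fused lysozyme insert). The `C` range is additionally
#' excluded from the intracellular-center computation (the C-terminal tail
#' extends into the cytosol and would drag the center away from the bundle).
#'
#' @param path path to the config file.
#' @param pocket_residues optional integer vector of pocket residue numbers,
#'   or a path to a one-column file of residue numbers.
#' @return An object of class `region_config`: list with `ranges`
#'   (data.frame label/start/end), `excluded_ranges`, `cterm_range`,
#'   `pocket_residues`.
#' @export
read_region_config <- function(path, pocket_residues = integer(0)) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("label", "start", "end") %in% names(tab)))
    stop("region config must have columns label, start, end")
  if (is.character(pocket_residues) && length(pocket_residues) == 1L)
    pocket_residues <- utils::read.table(pocket_residues, header = TRUE)[[1L]]
  region_config(ranges = tab[tab$label != "EXCLUDE", ],
                excluded_ranges = tab[tab$label == "EXCLUDE", c("start", "end")],
                pocket_residues = as.integer(pocket_residues))
}

#' Construct a region config
#'
#' @param ranges data.frame with columns `label`, `start`, `end`.
#' @param excluded_ranges data.frame with `start`, `end` (may be empty).
#' @param cterm_range length-2 vector; defaults to the `C` range in `ranges`.
#' @param pocket_residues integer vector of pocket residue numbers.
#' @return A `region_config`.
#' @export
region_config <- function(ranges, excluded_ranges = NULL, cterm_range = NULL,
                          pocket_residues = integer(0)) {
  bad <- setdiff(ranges$label, .REGION_LABELS)
  if (length(bad)) stop("unknown region labels: ", paste(bad, collapse = ", "))
  if (is.null(excluded_ranges))
    excluded_ranges <- data.frame(start = integer(0), end = integer(0))
  if (is.null(cterm_range)) {
    cr <- ranges[ranges$label == "C", ]
    cterm_range <- if (nrow(cr)) c(cr$start[1L], cr$end[1L]) else NULL
  }
  structure(list(ranges = ranges, excluded_ranges = excluded_ranges,
                 cterm_range = cterm_range,
                 pocket_residues = as.integer(pocket_residues)),
            class = "region_config")
}

.in_ranges <- function(resno, ranges) {
  if (is.null(ranges) || nrow(ranges) == 0L) return(rep(FALSE, length(resno)))
  out <- rep(FALSE, length(resno))
  for (k in seq_len(nrow(ranges)))
    out <- out | (resno >= ranges$start[k] & resno <= ranges$end[k])
  out
}

#' Region label of each residue
#'
#' @param resno integer vector of residue numbers.
#' @param cfg a `region_config`.
#' @return Character vector of labels (`NA` for unlabelled residues,
#'   `"excluded"` for residues in excluded ranges).
#' @export
region_of <- function(resno, cfg) {
  out <- rep(NA_character_, length(resno))
  for (k in seq_len(nrow(cfg$ranges))) {
    hit <- resno >= cfg$ranges$start[k] & resno <= cfg$ranges$end[k]
    out[hit] <- cfg$ranges$label[k]
  }
  out[.in_ranges(resno, cfg$excluded_ranges)] <- "excluded"
  out
}

#' Read Calpha coordinates of one chain from a PDB file
#'
#' Keeps one Calpha per residue number (first altloc); HETATM records and
#' waters are ignored; insertion codes are rejected. Residues present in the
#' chain without a Calpha atom are skipped with a warning.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier (default `"A"`).
#' @return An object of class `structure_model`: list with `resno` (integer
#'   vector, ordered) and `xyz` (n x 3 matrix, Angstrom, rownames = resno).
#' @export
read_structure <- function(path, chain = "A") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, ]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(ins)))
    stop("insertion codes present in chain ", chain,
         "; renumber the structure before use")
  ca <- at[at$elety == "CA", ]
  # first altloc per residue number
  ca <- ca[!duplicated(ca$resno), ]
  missing_ca <- setdiff(unique(at$resno), ca$resno)
  if (length(missing_ca))
    warning("residues without a Calpha skipped: ",
            paste(missing_ca, collapse = ", "))
  ca <- ca[order(ca$resno), ]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  rownames(xyz) <- ca$resno
  if (any(!is.finite(xyz))) stop("non-finite coordinates in ", path)
  structure(list(resno = as.integer(ca$resno), xyz = xyz, chain = chain),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d Calpha, chain %s, residues %d..%d\n",
              length(x$resno), x$chain, min(x$resno), max(x$resno)))
  invisible(x)
}

.center_of <- function(model, resno) {
  colMeans(model$xyz[as.character(resno), , drop = FALSE])
}

#' Build the extracellular-intracellular projection axis
#'
#' The extracellular center is the unweighted mean Calpha of the three ECLs
#' plus the N-terminal region; the intracellular center that of the three
#' ICLs, with the C-terminal range and any excluded ranges removed. The unit
#' vector points from the midpoint toward the extracellular center.
#'
#' @param model a `structure_model`.
#' @param cfg a `region_config`.
#' @return An object of class `projection_axis`: list with `center_extra`,
#'   `center_intra`, `midpoint`, `unit_vector`.
#' @export
compute_axis <- function(model, cfg) {
  lab <- region_of(model$resno, cfg)
  extra <- model$resno[lab %in% c("N", "ECL1", "ECL2", "ECL3")]
  intra <- model$resno[lab %in% c("ICL1", "ICL2", "ICL3")]
  if (!is.null(cfg$cterm_range))
    intra <- intra[intra < cfg$cterm_range[1L] | intra > cfg$cterm_range[2L]]
  if (length(extra) == 0L) stop("no residues in the extracellular region set")
  if (length(intra) == 0L) stop("no residues in the intracellular region set")
  ce <- .center_of(model, extra)
  ci <- .center_of(model, intra)
  d <- ce - ci
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) stop("degenerate-axis error: coincident geometric centers")
  structure(list(center_extra = ce, center_intra = ci,
                 midpoint = (ce + ci) / 2, unit_vector = d / nd),
            class = "projection_axis")
}

#' Project every residue onto the axis
#'
#' Signed inner product of the unit vector with the vector from the axis
#' midpoint to each Calpha. Positive scores lie on the extracellular side.
#' Residues in excluded ranges are dropped; C-terminal residues ARE projected
#' (they are excluded only from the center computation).
#'
#' @param model a `structure_model`.
#' @param axis a `projection_axis`.
#' @param cfg a `region_config`.
#' @return A `projection_result` data.frame with columns `residue`, `region`,
#'   `score` (Angstrom along the axis) and `selected` (all `FALSE`; see
#'   [mark_selected_residues()]).
#' @export
project_residues <- function(model, axis, cfg) {
  lab <- region_of(model$resno, cfg)
  keep <- is.na(lab) | lab != "excluded"
  resno <- model$resno[keep]
  disp <- sweep(model$xyz[keep, , drop = FALSE], 2L, axis$midpoint)
  structure(data.frame(residue = resno, region = lab[keep],
                       score = drop(disp %*% axis$unit_vector),
                       selected = FALSE, stringsAsFactors = FALSE),
            class = c("projection_result", "data.frame"))
}

#' Flag the residues corresponding to selected sites
#'
#' @param proj a `projection_result`.
#' @param residues integer vector of selected residue numbers (e.g.
#'   `table$ref_residue[table$selected]`).
#' @return The projection result with `selected` updated.
#' @export
mark_selected_residues <- function(proj, residues) {
  proj$selected <- proj$residue %in% residues
  proj
}

#' Distance from the axis midpoint to the TM-bundle center
#'
#' Euclidean distance between the axis midpoint and the unweighted mean
#' Calpha of the seven transmembrane helices. A small value indicates the
#' midpoint sits near the geometric center of the bundle (about 3.3 Angstrom
#' for CXCR4, PDB 3ODU).
#'
#' @param model a `structure_model`.
#' @param axis a `projection_axis`.
#' @param cfg a `region_config`.
#' @return Non-negative scalar (Angstrom).
#' @export
tm_center_distance <- function(model, axis, cfg) {
  lab <- region_of(model$resno, cfg)
  tm <- model$resno[lab %in% paste0("TM", 1:7)]
  if (length(tm) == 0L) stop("no TM residues labelled by the config")
  sqrt(sum((.center_of(model, tm) - axis$midpoint)^2))
}

#' Write a projection result as TSV
#'
#' @param proj a `projection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection_table <- function(proj, path) {
  utils::write.table(proj, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Download reference coordinates from the PDB
#'
#' Fetches a structure from RCSB (requires network access) for use as the
#' reference receptor, e.g. CXCR4 (PDB 3ODU).
#'
#' @param dest destination file path.
#' @param pdb_id four-character PDB identifier (default `"3ODU"`).
#' @return `dest`, invisibly.
#' @export
fetch_reference_structure <- function(dest, pdb_id = "3ODU") {
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(pdb_id))
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  invisible(dest)
}

#' Path to the packaged CXCR4 (3ODU, chain A) region config
#'
#' @return File path within the installed package.
#' @export
cxcr4_region_config_path <- function() {
  system.file("extdata", "cxcr4_3odu_regions.tsv", package = "klsite",
              mustWork = TRUE)
}

#' Path to the packaged CXCR4 pocket-residue list
#'
#' @return File path within the installed package.
#' @export
cxcr4_pocket_residues_path <- function() {
  system.file("extdata", "cxcr4_pocket_residues.tsv", package = "klsite",
              mustWork = TRUE)
}
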