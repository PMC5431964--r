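#' Per-cell species richness
#'
#' @param matrix binary occurrence matrix (species x cells).
#' @return named integer vector, one entry per cell (0 for empty cells).
#' @export
species_richness <- function(matrix) {
  stopifnot(is.matrix(matrix))
  colSums(matrix > 0)
}

#' Weighted and corrected weighted endemism per cell
#'
#' Weighted endemism is `WE = sum over the cell's species of 1/R_j`, where
#' `R_j` is the species' range size on the analysis grid; each species thus
#' contributes exactly 1 summed over all cells. Corrected weighted endemism
#' divides by the cell's richness and is expressed as a percentage,
#' `CWE = WE / S * 100`: the mean range-restriction of the cell's species,
#' 100 when every species in the cell is a single-cell endemic. Cells with
#' no species get `WE = 0` (an exact empty sum) and `CWE = NA`.
#'
#' @param matrix binary occurrence matrix (species x cells).
#' @return data frame with columns `cell_id`, `SR`, `WE`, `CWE_pct`.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("c1", "c2")))
#' corrected_weighted_endemism(m)  # c1: CWE = (1 + 1/2)/2 * 100 = 75
#' @export
corrected_weighted_endemism <- function(matrix) {
  stopifnot(is.matrix(matrix))
  rj <- range_sizes(matrix)
  if (any(rj == 0)) stop("species with empty ranges present; filter first", call. = FALSE)
  inc <- matrix > 0
  we <- colSums(inc / rj)
  sr <- colSums(inc)
  cwe <- ifelse(sr > 0, we / sr * 100, NA_real_)
  data.frame(cell_id = colnames(matrix), SR = as.integer(sr), WE = we,
             CWE_pct = cwe, row.names = NULL)
}

#' Per-cell Faith's PD and relative phylogenetic diversity
#'
#' Faith's PD of a cell is the sum of branch lengths on the union of
#' root-to-tip paths of the taxa recorded there (rooted convention; see
#' [faith_pd()]). Relative phylogenetic diversity divides PD by `log10(S)`
#' to damp the near-linear coupling of PD to richness: `PD_rel = PD /
#' log10(S)`. For `S = 1` the divisor is zero, so PD_rel is undefined; the
#' default flags such cells (excluding them from PD_rel hotspot ranking),
#' `pdrel_s1 = "zero"` reports 0 instead. Empty cells get `PD = NA`,
#' `PD_rel = NA` and an `empty` flag.
#'
#' @param tree a `phylo` object aligned with the matrix.
#' @param matrix binary occurrence matrix.
#' @param pdrel_s1 handling of single-species cells: `"undefined"` (NA,
#'   default) or `"zero"`.
#' @param rooted PD rooting convention, see [faith_pd()].
#' @return data frame with columns `cell_id`, `SR`, `PD`, `PD_rel`, `flags`.
#' @export
relative_phylogenetic_diversity <- function(tree, matrix,
                                            pdrel_s1 = c("undefined", "zero"),
                                            rooted = TRUE) {
  pdrel_s1 <- match.arg(pdrel_s1)
  check_aligned(tree, matrix)
  sr <- species_richness(matrix)
  pd <- cell_pd(tree, matrix, rooted = rooted)
  pd[sr == 0] <- NA_real_
  pd_rel <- ifelse(sr >= 2, pd / log10(sr), NA_real_)
  if (pdrel_s1 == "zero") pd_rel[sr == 1] <- 0
  flags <- character(length(sr))
  flags[sr == 1] <- "pdrel_undefined_s1"
  flags[sr == 0] <- "empty"
  data.frame(cell_id = colnames(matrix), SR = as.integer(sr), PD = pd,
             PD_rel = pd_rel, flags = flags, row.names = NULL)
}

# Rooted PD for every cell in one postorder sweep: an edge contributes its
# length to a cell iff any descendant tip occurs in the cell.
cell_pd <- function(tree, matrix, rooted = TRUE) {
  np <- node_presence(tree, matrix > 0)
  edge_pres <- np$presence[np$edge[, 2L], , drop = FALSE]
  if (!rooted) {
    # drop edges ancestral to all of a cell's taxa: edge contributes iff its
    # subtree holds some but not all of the cell's taxa
    counts <- matrix(0L, nrow = nrow(np$presence), ncol = ncol(matrix))
    counts[seq_len(np$ntip), ] <- matrix[tree$tip.label, , drop = FALSE]
    for (i in seq_len(nrow(np$edge))) {
      counts[np$edge[i, 1L], ] <- counts[np$edge[i, 1L], ] + counts[np$edge[i, 2L], ]
    }
    sr <- species_richness(matrix)
    sub <- counts[np$edge[, 2L], , drop = FALSE]
    edge_pres <- sub > 0L & sweep(sub, 2L, sr, "<")
  }
  stats::setNames(colSums(edge_pres * np$edge.length), colnames(matrix))
}

#' Per-cell phylogenetic endemism
#'
#' Phylogenetic endemism weights each branch on a cell's spanning paths by
#' the inverse of its clade range: `PE = sum over branches c of L_c / R_c`,
#' where `R_c` is the number of cells holding at least one descendant of
#' branch c (overlapping cells counted once). Branch lengths shared by
#' widespread clades are thus discounted, and summed over all cells each
#' branch contributes its length exactly once, so total PE equals the PD of
#' all recorded taxa. Empty cells have PE = 0 exactly.
#'
#' @param tree a `phylo` object aligned with the matrix.
#' @param matrix binary occurrence matrix.
#' @return data frame with columns `cell_id`, `PE`.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' m <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("c1", "c2")))
#' phylogenetic_endemism(tr, m)  # PE(c1) = 2, PE(c2) = 3
#' @export
phylogenetic_endemism <- function(tree, matrix) {
  check_aligned(tree, matrix)
  np <- node_presence(tree, matrix > 0)
  edge_pres <- np$presence[np$edge[, 2L], , drop = FALSE]
  rc <- rowSums(edge_pres)
  w <- ifelse(rc > 0, np$edge.length / rc, 0)
  pe <- colSums(edge_pres * w)
  data.frame(cell_id = colnames(matrix), PE = as.numeric(pe), row.names = NULL)
}

#' Compute the full per-cell diversity table
#'
#' One call computing all four per-cell metrics — SR, CWE (with WE kept
#' alongside for its conservation identity), Faith's PD with PD_rel, and PE
#' — plus per-cell flags (`empty`, `pdrel_undefined_s1`). Output order
#' follows the matrix columns and the values are invariant to row/column
#' permutations of the input.
#'
#' @inheritParams relative_phylogenetic_diversity
#' @return data frame with columns `cell_id`, `SR`, `WE`, `CWE_pct`, `PD`,
#'   `PD_rel`, `PE`, `flags`.
#' @export
diversity_table <- function(tree, matrix, pdrel_s1 = c("undefined", "zero"),
                            rooted = TRUE) {
  pdrel_s1 <- match.arg(pdrel_s1)
  check_aligned(tree, matrix)
  cwe <- corrected_weighted_endemism(matrix)
  pdr <- relative_phylogenetic_diversity(tree, matrix, pdrel_s1 = pdrel_s1,
                                         rooted = rooted)
  pe <- phylogenetic_endemism(tree, matrix)
  out <- cbind(cwe, pdr[, c("PD", "PD_rel", "flags")], PE = pe$PE)
  rownames(out) <- NULL
  out[, c("cell_id", "SR", "WE", "CWE_pct", "PD", "PD_rel", "PE", "flags")]
}
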