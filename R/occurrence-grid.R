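#' Read a grid-cell attribute table
#'
#' Expects a CSV with at least `cell_id` and `land_area_km2` (or `land_area`)
#' columns; `reserve_area_km2`/`reserve_area`, `row` and `col` are optional.
#' Cells with reserve area exceeding land area are clamped with a warning
#' (digitisation slivers), never silently accepted or rejected.
#'
#' @param path CSV file path.
#' @return a data frame with columns `cell_id`, `row`, `col` (NA when
#'   absent), `land_area`, `reserve_area`.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  if ("land_area_km2" %in% nm && !"land_area" %in% nm) {
    names(df)[nm == "land_area_km2"] <- "land_area"
  }
  nm <- names(df)
  if ("reserve_area_km2" %in% nm && !"reserve_area" %in% nm) {
    names(df)[nm == "reserve_area_km2"] <- "reserve_area"
  }
  if (!"row" %in% names(df)) df$row <- NA_integer_
  if (!"col" %in% names(df)) df$col <- NA_integer_
  validate_cells(df)
}

#' Load a species-by-cell occurrence matrix from long-format records
#'
#' Reads presence records (`species_id`, `cell_id`), deduplicates them,
#' drops records referencing cells absent from the cell table (with a
#' message giving the count), and returns a binary incidence matrix.
#' Species ids are matched exactly after trimming and collapsing internal
#' whitespace.
#'
#' @param path CSV with columns `species_id` and `cell_id`, or a data frame
#'   with those columns.
#' @param cells a validated cell table (see [read_cells()]).
#' @return an integer matrix with species as rows (dimnames set), cells as
#'   columns covering every cell in `cells`, entries 0/1.
#' @export
load_occurrences <- function(path, cells) {
  cells <- validate_cells(cells)
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "cell_id") %in% names(df))) {
    stop("occurrence input needs columns species_id and cell_id", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("occurrence input is empty", call. = FALSE)
  df$species_id <- normalize_species_id(df$species_id)
  df$cell_id <- as.character(df$cell_id)

  unknown <- !(df$cell_id %in% cells$cell_id)
  if (any(unknown)) {
    message("dropping ", sum(unknown),
            " occurrence record(s) referencing cells absent from the cell table")
    df <- df[!unknown, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no occurrence records left after cell matching", call. = FALSE)
  dup <- duplicated(df[, c("species_id", "cell_id")])
  if (any(dup)) df <- df[!dup, , drop = FALSE]

  species <- sort(unique(df$species_id))
  mat <- matrix(0L, nrow = length(species), ncol = nrow(cells),
                dimnames = list(species, cells$cell_id))
  mat[cbind(match(df$species_id, species), match(df$cell_id, cells$cell_id))] <- 1L
  mat
}

#' Species range sizes on the analysis grid
#'
#' The range size of a species is the number of grid cells in which it is
#' recorded — the row sum of the binary incidence matrix.
#'
#' @param matrix binary occurrence matrix (species x cells).
#' @return named integer vector of range sizes.
#' @export
range_sizes <- function(matrix) {
  stopifnot(is.matrix(matrix))
  rowSums(matrix > 0)
}

#' Exclude small cells and prune the occurrence matrix accordingly
#'
#' Removes grid cells whose land area is strictly below `min_land_area`
#' (incomplete coastal/border cells), drops the corresponding matrix
#' columns, and removes species left with an empty range, reporting counts.
#' Range sizes downstream (`1/R_j` weights, clade ranges) then refer to the
#' filtered analysis grid.
#'
#' @param cells cell table.
#' @param matrix binary occurrence matrix whose columns cover `cells$cell_id`.
#' @param min_land_area km² threshold; cells with `land_area <
#'   min_land_area` are excluded. Default 1250 (half a 2500 km² cell).
#' @return list with elements `cells` and `matrix`, both filtered.
#' @export
filter_cells <- function(cells, matrix, min_land_area = 1250) {
  cells <- validate_cells(cells)
  stopifnot(is.matrix(matrix), min_land_area >= 0)
  keep <- cells$land_area >= min_land_area
  if (!any(keep)) stop("all cells fall below min_land_area", call. = FALSE)
  if (any(!keep)) {
    message("excluding ", sum(!keep), " cell(s) with land area below ",
            min_land_area, " km2")
  }
  cells <- cells[keep, , drop = FALSE]
  rownames(cells) <- NULL
  matrix <- matrix[, cells$cell_id, drop = FALSE]
  empty <- rowSums(matrix) == 0
  if (any(empty)) {
    message("dropping ", sum(empty),
            " species with no occurrences on the filtered grid")
    matrix <- matrix[!empty, , drop = FALSE]
  }
  if (nrow(matrix) == 0L) stop("no species left after cell filtering", call. = FALSE)
  list(cells = cells, matrix = matrix)
}

#' Align an occurrence matrix with a phylogeny
#'
#' Restricts the matrix to species present as tree tips and prunes the tree
#' to species present in the matrix, reporting the number of names dropped
#' on each side. Pruning collapses the resulting unifurcations and sums the
#' adjacent branch lengths (via [ape::keep.tip()]), so total path lengths to
#' retained tips are preserved.
#'
#' @param matrix binary occurrence matrix.
#' @param tree a `phylo` object.
#' @return list with elements `matrix` and `tree`, name-aligned.
#' @export
align_taxa <- function(matrix, tree) {
  stopifnot(is.matrix(matrix), inherits(tree, "phylo"))
  shared <- intersect(rownames(matrix), tree$tip.label)
  if (length(shared) == 0L) {
    stop("no species shared between occurrence matrix and tree", call. = FALSE)
  }
  n_mat_only <- nrow(matrix) - length(shared)
  n_tree_only <- length(tree$tip.label) - length(shared)
  if (n_mat_only > 0L) {
    message("dropping ", n_mat_only, " matrix species absent from the tree")
  }
  if (n_tree_only > 0L) {
    message("pruning ", n_tree_only, " tree tips absent from the matrix")
    tree <- ape::keep.tip(tree, shared)
  }
  list(matrix = matrix[shared, , drop = FALSE], tree = tree)
}
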