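#' Select the top-fraction hotspot cells for one diversity metric
#'
#' Ranks the eligible cells (those with a defined value for the metric) and
#' selects the top `ceiling(p * n_eligible)` of them, extended to every cell
#' tied with the cutoff value, so the result is deterministic and invariant
#' to input order. `mode = "range"` instead implements the literal
#' value-range reading — cells whose value falls in the top `p` fraction of
#' the observed range `[min, max]` — for sensitivity analysis.
#'
#' @param table a diversity table from [diversity_table()].
#' @param metric column name to rank on (e.g. `"SR"`, `"CWE_pct"`,
#'   `"PD_rel"`, `"PE"`).
#' @param p threshold fraction in (0, 1); 0.05 and 0.10 are conventional.
#' @param mode `"cells"` (top fraction of cells, default) or `"range"`.
#' @return an object of class `hotspot_set`: list with `metric`, `p`,
#'   `mode`, `cells` (character vector of selected cell ids), `cutoff`, and
#'   `n_eligible`.
#' @export
select_hotspots <- function(table, metric, p, mode = c("cells", "range")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(table), "cell_id" %in% names(table),
            metric %in% names(table), length(p) == 1L, p > 0, p < 1)
  vals <- table[[metric]]
  ok <- !is.na(vals)
  if (!any(ok)) stop("no cells with a defined value for metric ", metric, call. = FALSE)
  v <- vals[ok]
  ids <- as.character(table$cell_id[ok])
  if (mode == "cells") {
    k <- ceiling(p * length(v))
    cutoff <- sort(v, decreasing = TRUE)[k]
  } else {
    cutoff <- min(v) + (1 - p) * (max(v) - min(v))
  }
  sel <- ids[v >= cutoff]
  structure(list(metric = metric, p = p, mode = mode,
                 cells = sort(sel), cutoff = cutoff, n_eligible = length(v)),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("Hotspot set:", x$metric, sprintf("(top %.0f%% of %d eligible cells, %s mode)\n",
      100 * x$p, x$n_eligible, x$mode))
  cat("  ", length(x$cells), " cells selected, cutoff value ",
      format(x$cutoff), "\n", sep = "")
  invisible(x)
}

#' Per-cell count of metrics selecting each hotspot cell
#'
#' @param sets list of `hotspot_set` objects (typically one per metric at a
#'   common threshold).
#' @return data frame `cell_id`, `n_metrics` over the union of all sets.
#' @export
hotspot_union <- function(sets) {
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "hotspot_set")))
  all_cells <- sort(unique(unlist(lapply(sets, `[[`, "cells"))))
  counts <- Reduce(`+`, lapply(sets, function(s) as.integer(all_cells %in% s$cells)))
  data.frame(cell_id = all_cells, n_metrics = as.integer(counts))
}

#' Multi-metric hotspot overlap accounting
#'
#' Mirrors the bookkeeping of multi-index hotspot studies: the union of all
#' per-metric hotspot sets (cell count, land area and its fraction of the
#' study area), per-n-metric intersection counts (how many cells were
#' selected by exactly n metrics), species coverage of the union and of each
#' set, species unique to each metric's set ("distinct species"), and
#' pairwise overlap. Because published overlap percentages rarely state
#' their denominator, two spatial conventions are reported side by side —
#' Jaccard `|A∩B|/|A∪B|` and `|A∩B|/min(|A|,|B|)` — and species-composition
#' similarity is given as both Sørensen and Jaccard.
#'
#' @param sets list of `hotspot_set` objects (>= 2) on the same cell universe.
#' @param cells cell table covering all selected cells.
#' @param matrix binary occurrence matrix on the same cells.
#' @return an object of class `hotspot_overlap`: list with components
#'   `union` (count/area/fractions), `per_n` (data frame), `species`
#'   (per-set and union coverage), `distinct_species` (named list), and
#'   `pairwise` (data frame).
#' @export
overlap_summary <- function(sets, cells, matrix) {
  stopifnot(length(sets) >= 2L, all(vapply(sets, inherits, TRUE, "hotspot_set")))
  cells <- validate_cells(cells)
  stopifnot(is.matrix(matrix))
  bad <- unlist(lapply(sets, function(s) setdiff(s$cells, cells$cell_id)))
  if (length(bad) > 0L) {
    stop("hotspot cells absent from the cell table: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  uni <- hotspot_union(sets)
  area <- function(id) sum(cells$land_area[match(id, cells$cell_id)])
  total_area <- sum(cells$land_area)
  n_sp <- nrow(matrix)
  species_in <- function(id) {
    rownames(matrix)[rowSums(matrix[, intersect(colnames(matrix), id), drop = FALSE]) > 0]
  }

  nm <- vapply(sets, `[[`, character(1L), "metric")
  per_set_species <- lapply(sets, function(s) species_in(s$cells))
  names(per_set_species) <- nm
  distinct <- lapply(seq_along(sets), function(i) {
    setdiff(per_set_species[[i]], unique(unlist(per_set_species[-i])))
  })
  names(distinct) <- nm

  max_n <- length(sets)
  per_n <- data.frame(n_metrics = seq_len(max_n))
  per_n$n_cells <- vapply(per_n$n_metrics,
                          function(n) sum(uni$n_metrics == n), integer(1L))
  per_n$land_area <- vapply(per_n$n_metrics, function(n) {
    area(uni$cell_id[uni$n_metrics == n])
  }, numeric(1L))
  per_n$fraction_of_union <- per_n$n_cells / nrow(uni)

  pairs <- utils::combn(seq_along(sets), 2L)
  pw <- data.frame(
    metric_a = nm[pairs[1L, ]], metric_b = nm[pairs[2L, ]],
    jaccard_pct = NA_real_, overlap_min_pct = NA_real_,
    sorensen_species_pct = NA_real_, jaccard_species_pct = NA_real_
  )
  for (k in seq_len(ncol(pairs))) {
    a <- sets[[pairs[1L, k]]]$cells
    b <- sets[[pairs[2L, k]]]$cells
    i <- length(intersect(a, b))
    u <- length(union(a, b))
    pw$jaccard_pct[k] <- 100 * i / u
    pw$overlap_min_pct[k] <- 100 * i / min(length(a), length(b))
    sa <- per_set_species[[pairs[1L, k]]]
    sb <- per_set_species[[pairs[2L, k]]]
    si <- length(intersect(sa, sb))
    pw$sorensen_species_pct[k] <- 100 * 2 * si / (length(sa) + length(sb))
    pw$jaccard_species_pct[k] <- 100 * si / length(union(sa, sb))
  }

  union_species <- species_in(uni$cell_id)
  structure(list(
    union = list(
      cells = uni,
      n_cells = nrow(uni),
      land_area = area(uni$cell_id),
      land_fraction = area(uni$cell_id) / total_area
    ),
    per_n = per_n,
    species = list(
      n_total = n_sp,
      union_count = length(union_species),
      union_fraction = length(union_species) / n_sp,
      per_set = data.frame(
        metric = nm,
        n_species = vapply(per_set_species, length, integer(1L)),
        fraction = vapply(per_set_species, length, integer(1L)) / n_sp,
        n_cells = vapply(sets, function(s) length(s$cells), integer(1L))
      )
    ),
    distinct_species = distinct,
    pairwise = pw
  ), class = "hotspot_overlap")
}

#' @export
print.hotspot_overlap <- function(x, ...) {
  cat("Hotspot overlap across", nrow(x$species$per_set), "metrics\n")
  cat(sprintf("  union: %d cells, %.4g km2 (%.2f%% of study area), %d/%d species (%.2f%%)\n",
              x$union$n_cells, x$union$land_area, 100 * x$union$land_fraction,
              x$species$union_count, x$species$n_total,
              100 * x$species$union_fraction))
  cat("  cells by number of selecting metrics:\n")
  print(x$per_n, row.names = FALSE)
  cat("  pairwise overlap:\n")
  print(x$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Group hotspot cells into contiguous regions
#'
#' Labels maximal connected components of a cell set under rook (edge) or
#' queen (edge-or-corner, default) adjacency on the grid's row/col
#' coordinates. Queen adjacency is the default because mountain-chain
#' hotspot complexes commonly run diagonally across a grid. Singleton
#' regions are allowed.
#'
#' @param hotspot_cells character vector of cell ids (e.g. the union of the
#'   per-metric sets).
#' @param cells cell table with `row` and `col` populated.
#' @param adjacency `"queen"` (default) or `"rook"`.
#' @return list with `membership` (data frame `cell_id`, `region_id`, region
#'   ids ordered by decreasing region size then by smallest cell id) and
#'   `regions` (data frame `region_id`, `n_cells`, `land_area`).
#' @export
label_regions <- function(hotspot_cells, cells, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  cells <- validate_cells(cells)
  hotspot_cells <- sort(unique(as.character(hotspot_cells)))
  idx <- match(hotspot_cells, cells$cell_id)
  if (anyNA(idx)) stop("hotspot cells absent from cell table", call. = FALSE)
  rc <- cells[idx, c("row", "col")]
  if (anyNA(rc$row) || anyNA(rc$col)) {
    stop("region labeling requires row/col coordinates for every hotspot cell",
         call. = FALSE)
  }
  n <- length(hotspot_cells)
  # pairwise adjacency on the (small) hotspot set
  dr <- abs(outer(rc$row, rc$row, "-"))
  dc <- abs(outer(rc$col, rc$col, "-"))
  adj <- if (adjacency == "queen") (dr <= 1 & dc <= 1) else (dr + dc == 1)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # deterministic region ids: by decreasing size, ties by smallest member id
  sizes <- table(comp)
  first <- tapply(hotspot_cells, comp, min)
  ord <- order(-as.integer(sizes), first)
  relabel <- match(comp, as.integer(names(sizes))[ord])
  membership <- data.frame(cell_id = hotspot_cells, region_id = relabel)
  regions <- data.frame(
    region_id = sort(unique(relabel)),
    n_cells = as.integer(table(relabel)),
    land_area = as.numeric(tapply(cells$land_area[idx], relabel, sum))
  )
  list(membership = membership, regions = regions)
}

#' Species/genus and species/family ratios for a hotspot region
#'
#' Diversification-style ratios over the pooled species of a region's cells:
#' the number of species divided by the number of distinct genera, and by
#' the number of distinct families.
#'
#' @param region_cells character vector of the region's cell ids.
#' @param matrix binary occurrence matrix.
#' @param taxonomy data frame with columns `species_id`, `genus`, `family`
#'   covering every species recorded in the region.
#' @return list with `n_species`, `n_genera`, `n_families`,
#'   `species_genus_ratio`, `species_family_ratio`.
#' @export
region_taxon_ratios <- function(region_cells, matrix, taxonomy) {
  stopifnot(is.matrix(matrix), is.data.frame(taxonomy),
            all(c("species_id", "genus", "family") %in% names(taxonomy)))
  cols <- intersect(colnames(matrix), as.character(region_cells))
  sp <- rownames(matrix)[rowSums(matrix[, cols, drop = FALSE]) > 0]
  if (length(sp) == 0L) stop("region contains no species", call. = FALSE)
  hit <- match(sp, normalize_species_id(taxonomy$species_id))
  if (anyNA(hit)) {
    stop("species without taxonomy mapping: ",
         paste(sp[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  ng <- length(unique(taxonomy$genus[hit]))
  nf <- length(unique(taxonomy$family[hit]))
  list(n_species = length(sp), n_genera = ng, n_families = nf,
       species_genus_ratio = length(sp) / ng,
       species_family_ratio = length(sp) / nf)
}
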