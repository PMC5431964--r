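#' Configuration for the synthetic study generator
#'
#' Bundles the parameters of the synthetic landscape, phylogeny and
#' occurrence generator with validated defaults. The defaults emulate a
#' gridded national atlas study: 50 km x 50 km cells (2500 km²), a
#' right-skewed lognormal range-size distribution in which most species are
#' narrow-ranged, a monotone richness gradient along the row axis standing
#' in for the latitudinal gradient, localized endemism centers, and
#' zero-inflated Beta reserve coverage averaging roughly a tenth of each
#' cell.
#'
#' @param n_rows,n_cols grid dimensions (rows x columns).
#' @param cell_area km² per full cell (default 2500 = 50 km x 50 km).
#' @param n_species number of species (tree tips).
#' @param range_size_log_mean,range_size_log_sd lognormal parameters of the
#'   species range-size distribution, in cells (defaults: median 10 cells,
#'   sdlog 1.2).
#' @param n_endemism_centers number of endemism-center cells sampled when
#'   `endemism_center_cells` is not given.
#' @param endemism_center_cells optional explicit cell ids acting as
#'   endemism centers (lets tests plant known hotspots).
#' @param n_planted_endemics number of species forced to single-cell ranges
#'   placed on the endemism centers (cycled), default 0.
#' @param endemism_quantile range-size quantile below which (non-planted)
#'   species are treated as narrow-ranged and attracted to endemism centers.
#' @param endemism_bias probability a narrow-ranged species starts its range
#'   at an endemism center.
#' @param richness_gradient_strength non-negative strength of the monotone
#'   trend of expected richness along the row axis (0 = flat).
#' @param richness_block_cells optional explicit cell ids forming a planted
#'   high-richness block where widespread species preferentially start.
#' @param block_bias probability a widespread species starts inside
#'   `richness_block_cells` when that block is given.
#' @param border_truncation_prob probability a border cell gets a land area
#'   drawn uniformly below `cell_area` (emulating incomplete coastal/border
#'   cells and exercising the land-area exclusion rule).
#' @param reserve_coverage_beta_a,reserve_coverage_beta_b Beta parameters of
#'   the per-cell reserve coverage fraction.
#' @param reserve_zero_prob probability a cell has zero reserve coverage.
#' @param seed integer RNG seed (< 2^30); identical config + seed gives
#'   bit-identical outputs.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 20, n_cols = 25, cell_area = 2500,
                             n_species = 200,
                             range_size_log_mean = log(10),
                             range_size_log_sd = 1.2,
                             n_endemism_centers = 3,
                             endemism_center_cells = NULL,
                             n_planted_endemics = 0,
                             endemism_quantile = 0.25,
                             endemism_bias = 0.8,
                             richness_gradient_strength = 2,
                             richness_block_cells = NULL,
                             block_bias = 0.5,
                             border_truncation_prob = 0.3,
                             reserve_coverage_beta_a = 0.9,
                             reserve_coverage_beta_b = 4.5,
                             reserve_zero_prob = 0.35,
                             seed = 1) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_area = cell_area, n_species = as.integer(n_species),
              range_size_log_mean = range_size_log_mean,
              range_size_log_sd = range_size_log_sd,
              n_endemism_centers = as.integer(n_endemism_centers),
              endemism_center_cells = endemism_center_cells,
              n_planted_endemics = as.integer(n_planted_endemics),
              endemism_quantile = endemism_quantile,
              endemism_bias = endemism_bias,
              richness_gradient_strength = richness_gradient_strength,
              richness_block_cells = richness_block_cells,
              block_bias = block_bias,
              border_truncation_prob = border_truncation_prob,
              reserve_coverage_beta_a = reserve_coverage_beta_a,
              reserve_coverage_beta_b = reserve_coverage_beta_b,
              reserve_zero_prob = reserve_zero_prob,
              seed = as.integer(seed))
  if (cfg$n_rows < 1L || cfg$n_cols < 1L) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  if (cfg$n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  if (cfg$cell_area <= 0) stop("cell_area must be positive", call. = FALSE)
  probs <- c(cfg$endemism_quantile, cfg$endemism_bias, cfg$block_bias,
             cfg$border_truncation_prob, cfg$reserve_zero_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$richness_gradient_strength < 0) {
    stop("richness_gradient_strength must be >= 0", call. = FALSE)
  }
  if (cfg$range_size_log_sd < 0) stop("range_size_log_sd must be >= 0", call. = FALSE)
  if (abs(cfg$seed) >= 2^30) stop("seed must have magnitude below 2^30", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

grid_cell_id <- function(row, col) sprintf("c%d_%d", row, col)

#' Generate a synthetic grid-cell table
#'
#' Builds a rectangular grid of cells (row-major), each of `cell_area` km².
#' A configurable fraction of the border cells has its land area drawn
#' uniformly below `cell_area`, emulating incomplete coastal/border cells.
#' Reserve area is a zero-inflated Beta fraction of each cell's land area.
#'
#' @param config a [synthetic_config()].
#' @return a cell table data frame: `cell_id`, `row`, `col`, `land_area`,
#'   `reserve_area`.
#' @export
generate_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    rc <- expand.grid(col = seq_len(config$n_cols), row = seq_len(config$n_rows))
    cells <- data.frame(cell_id = grid_cell_id(rc$row, rc$col),
                        row = rc$row, col = rc$col,
                        land_area = config$cell_area,
                        reserve_area = 0)
    border <- cells$row %in% c(1L, config$n_rows) |
      cells$col %in% c(1L, config$n_cols)
    truncated <- border & stats::runif(nrow(cells)) < config$border_truncation_prob
    cells$land_area[truncated] <-
      stats::runif(sum(truncated)) * config$cell_area
    covered <- stats::runif(nrow(cells)) >= config$reserve_zero_prob
    frac <- numeric(nrow(cells))
    frac[covered] <- stats::rbeta(sum(covered), config$reserve_coverage_beta_a,
                                  config$reserve_coverage_beta_b)
    cells$reserve_area <- frac * cells$land_area
    cells
  })
}

#' Generate a random ultrametric Yule phylogeny
#'
#' Pure-birth (Yule) tree with `n_species` tips, ultrametric by
#' construction, tips labeled `sp_0001`, `sp_0002`, ...
#'
#' @param n_species number of tips (>= 1).
#' @param seed integer RNG seed.
#' @return a `phylo` object.
#' @export
generate_phylogeny <- function(n_species, seed = 1) {
  n_species <- as.integer(n_species)
  if (n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  width <- max(4L, nchar(n_species))
  labels <- sprintf(paste0("sp_%0", width, "d"), seq_len(n_species))
  if (n_species == 1L) {
    return(read_newick(text = paste0("(", labels, ":1);")))
  }
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    tree$tip.label <- labels
    tree
  })
}

# Rook-adjacency neighbor list on a row-major grid, by cell index.
rook_neighbors <- function(n_rows, n_cols) {
  idx <- function(r, c) (r - 1L) * n_cols + c
  lapply(seq_len(n_rows * n_cols), function(i) {
    r <- (i - 1L) %/% n_cols + 1L
    c <- (i - 1L) %% n_cols + 1L
    nb <- integer(0)
    if (r > 1L) nb <- c(nb, idx(r - 1L, c))
    if (r < n_rows) nb <- c(nb, idx(r + 1L, c))
    if (c > 1L) nb <- c(nb, idx(r, c - 1L))
    if (c < n_cols) nb <- c(nb, idx(r, c + 1L))
    nb
  })
}

# Breadth-first accretion: grow a contiguous range from `start` to `size`
# cells by repeatedly absorbing a uniformly chosen frontier cell.
grow_range <- function(start, size, neighbors, n_cells) {
  occupied <- logical(n_cells)
  occupied[start] <- TRUE
  count <- 1L
  frontier <- neighbors[[start]]
  while (count < size && length(frontier) > 0L) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    occupied[pick] <- TRUE
    count <- count + 1L
    frontier <- unique(c(frontier, neighbors[[pick]]))
    frontier <- frontier[!occupied[frontier]]
  }
  which(occupied)
}

#' Generate a synthetic occurrence matrix with cohesive species ranges
#'
#' Each species draws a range size from the configured lognormal (rounded
#' and clamped to `[1, n_cells]`) and grows a spatially contiguous range by
#' seeded breadth-first accretion on rook adjacency from a start cell.
#' Start cells are biased toward endemism centers for the narrowest
#' range-size quantile of species and toward the high end of the richness
#' gradient (higher rows) otherwise; planted endemics are pinned to the
#' endemism centers with single-cell ranges, and a planted high-richness
#' block, when configured, attracts the starts of widespread species. Every
#' species occupies at least one cell and every range is rook-connected.
#'
#' Draws come from a dedicated stream seeded with `config$seed + 1`, so grid
#' and occurrence randomness are decoupled.
#'
#' @param grid cell table from [generate_grid()] (the full grid; exclusion
#'   of small cells happens downstream in [filter_cells()]).
#' @param tree phylogeny whose tips define the species set.
#' @param config a [synthetic_config()].
#' @return binary integer matrix, species x cells.
#' @export
generate_occurrences <- function(grid, tree, config) {
  stopifnot(inherits(config, "synthetic_config"), inherits(tree, "phylo"))
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  species <- tree$tip.label
  n_sp <- length(species)
  n_cells <- nrow(grid)
  if (n_cells != config$n_rows * config$n_cols) {
    stop("grid does not match config dimensions", call. = FALSE)
  }
  neighbors <- rook_neighbors(config$n_rows, config$n_cols)

  with_seed(config$seed + 1L, {
    centers <- config$endemism_center_cells
    if (is.null(centers) && config$n_endemism_centers > 0L) {
      centers <- grid$cell_id[sample.int(n_cells, config$n_endemism_centers)]
    }
    center_idx <- match(centers, grid$cell_id)
    if (anyNA(center_idx)) {
      stop("endemism_center_cells not found in grid", call. = FALSE)
    }
    block_idx <- NULL
    if (!is.null(config$richness_block_cells)) {
      block_idx <- match(config$richness_block_cells, grid$cell_id)
      if (anyNA(block_idx)) stop("richness_block_cells not found in grid", call. = FALSE)
    }

    sizes <- pmin(pmax(round(stats::rlnorm(n_sp, config$range_size_log_mean,
                                           config$range_size_log_sd)), 1L), n_cells)
    n_plant <- min(config$n_planted_endemics, n_sp)
    if (n_plant > 0L) {
      if (length(center_idx) == 0L) {
        stop("planted endemics require endemism centers", call. = FALSE)
      }
      sizes[seq_len(n_plant)] <- 1L
    }
    free <- setdiff(seq_len(n_sp), seq_len(n_plant))
    narrow_cut <- stats::quantile(sizes[free], config$endemism_quantile,
                                  names = FALSE, type = 7)

    # gradient weights: expected richness rises with row index
    rownorm <- (grid$row - 1) / max(1L, config$n_rows - 1L)
    wgrad <- exp(config$richness_gradient_strength * rownorm)

    mat <- matrix(0L, nrow = n_sp, ncol = n_cells,
                  dimnames = list(species, grid$cell_id))
    for (j in seq_len(n_sp)) {
      if (j <= n_plant) {
        start <- center_idx[(j - 1L) %% length(center_idx) + 1L]
        mat[j, start] <- 1L
        next
      }
      narrow <- sizes[j] <= narrow_cut
      if (narrow && length(center_idx) > 0L &&
          stats::runif(1) < config$endemism_bias) {
        start <- center_idx[sample.int(length(center_idx), 1L)]
      } else if (!narrow && !is.null(block_idx) &&
                 stats::runif(1) < config$block_bias) {
        start <- block_idx[sample.int(length(block_idx), 1L)]
      } else {
        start <- sample.int(n_cells, 1L, prob = wgrad)
      }
      mat[j, grow_range(start, sizes[j], neighbors, n_cells)] <- 1L
    }
    mat
  })
}

#' Generate a complete synthetic study
#'
#' Runs [generate_grid()], [generate_phylogeny()] and
#' [generate_occurrences()] under one configuration and optionally writes
#' the three inputs as plain-text files (cells CSV, Newick tree, long-format
#' occurrence CSV).
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; created if missing.
#' @return list with `cells`, `tree`, `matrix` and the echoed `config`.
#' @export
simulate_dataset <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cells <- generate_grid(config)
  tree <- generate_phylogeny(config$n_species, seed = config$seed)
  mat <- generate_occurrences(cells, tree, config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out_cells <- data.frame(cell_id = cells$cell_id, row = cells$row,
                            col = cells$col, land_area_km2 = cells$land_area,
                            reserve_area_km2 = cells$reserve_area)
    utils::write.csv(out_cells, file.path(dir, "cells.csv"), row.names = FALSE)
    write_newick(tree, file.path(dir, "tree.nwk"))
    occ <- which(mat > 0, arr.ind = TRUE)
    long <- data.frame(species_id = rownames(mat)[occ[, 1L]],
                       cell_id = colnames(mat)[occ[, 2L]])
    long <- long[order(long$species_id, long$cell_id), ]
    utils::write.csv(long, file.path(dir, "occurrences.csv"), row.names = FALSE)
  }
  list(cells = cells, tree = tree, matrix = mat, config = config)
}
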