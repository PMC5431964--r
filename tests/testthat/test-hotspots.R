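div_fixture <- function(values, metric = "SR") {
  df <- data.frame(cell_id = sprintf("x%04d", seq_along(values)))
  df[[metric]] <- values
  df
}

test_that("top-fraction selection picks exactly the largest cells with distinct values", {
  div <- div_fixture(1:100)
  hs <- select_hotspots(div, "SR", 0.10)
  expect_length(hs$cells, 10)
  expect_setequal(hs$cells, sprintf("x%04d", 91:100))

  # shuffled input gives the identical set
  shuffled <- div[sample(nrow(div)), ]
  expect_identical(select_hotspots(shuffled, "SR", 0.10)$cells, hs$cells)
})

test_that("ties straddling the cutoff are all selected, never arbitrarily dropped", {
  vals <- c(rep(5, 3), rep(1, 97))
  hs <- select_hotspots(div_fixture(vals), "SR", 0.01)
  expect_length(hs$cells, 3)
  expect_setequal(hs$cells, sprintf("x%04d", 1:3))
})

test_that("selection is monotone in p and respects eligibility", {
  set.seed(17)
  vals <- rnorm(200)
  vals[sample(200, 20)] <- NA  # undefined metric values are ineligible
  div <- div_fixture(vals, metric = "PD_rel")
  ps <- c(0.02, 0.05, 0.10, 0.25)
  sets <- lapply(ps, function(p) select_hotspots(div, "PD_rel", p))
  for (k in seq_len(length(ps) - 1L)) {
    expect_true(all(sets[[k]]$cells %in% sets[[k + 1L]]$cells))
  }
  expect_equal(sets[[1]]$n_eligible, 180)
  expect_gte(length(sets[[3]]$cells), floor(0.10 * 180))
  # every selected value >= every unselected eligible value
  sel <- div$cell_id %in% sets[[3]]$cells
  expect_gte(min(div$PD_rel[sel], na.rm = TRUE),
             max(div$PD_rel[!sel & !is.na(div$PD_rel)]))
  expect_error(select_hotspots(div_fixture(rep(NA_real_, 5), "PE"), "PE", 0.1),
               "no cells")
})

test_that("range mode thresholds on the top fraction of the value range", {
  div <- div_fixture(c(0, 50, 89, 90, 95, 100))
  hs <- select_hotspots(div, "SR", 0.10, mode = "range")
  expect_setequal(hs$cells, div$cell_id[div$SR >= 90])
})

test_that("overlap accounting matches a brute-force set-algebra oracle", {
  set.seed(41)
  cells <- grid_fixture(10, 20)
  n_sp <- 30
  mat <- matrix(as.integer(runif(n_sp * 200) < 0.1), nrow = n_sp,
                dimnames = list(paste0("s", 1:n_sp), cells$cell_id))
  mat[, 1] <- 1L
  sets <- lapply(c("m1", "m2", "m3", "m4"), function(m) {
    structure(list(metric = m, p = 0.1, mode = "cells",
                   cells = sort(sample(cells$cell_id, sample(20:60, 1))),
                   cutoff = NA_real_, n_eligible = 200),
              class = "hotspot_set")
  })
  ov <- overlap_summary(sets, cells, mat)

  universe <- lapply(sets, `[[`, "cells")
  union_oracle <- sort(unique(unlist(universe)))
  expect_equal(ov$union$n_cells, length(union_oracle))
  expect_equal(ov$union$land_area, 2500 * length(union_oracle))
  # per-n counts by direct membership counting, and they total the union
  member_count <- sapply(union_oracle, function(id) {
    sum(vapply(universe, function(u) id %in% u, logical(1)))
  })
  for (n in 1:4) {
    expect_equal(ov$per_n$n_cells[ov$per_n$n_metrics == n],
                 sum(member_count == n))
  }
  expect_equal(sum(ov$per_n$n_cells), ov$union$n_cells)
  # pairwise percentages against direct set algebra
  for (k in seq_len(nrow(ov$pairwise))) {
    a <- universe[[match(ov$pairwise$metric_a[k], c("m1", "m2", "m3", "m4"))]]
    b <- universe[[match(ov$pairwise$metric_b[k], c("m1", "m2", "m3", "m4"))]]
    expect_equal(ov$pairwise$jaccard_pct[k],
                 100 * length(intersect(a, b)) / length(union(a, b)))
    expect_equal(ov$pairwise$overlap_min_pct[k],
                 100 * length(intersect(a, b)) / min(length(a), length(b)))
  }
})

test_that("identical and disjoint hotspot sets give the boundary overlaps", {
  cells <- grid_fixture(5, 8)
  mat <- matrix(1L, 2, 40, dimnames = list(c("s1", "s2"), cells$cell_id))
  mk <- function(metric, ids) {
    structure(list(metric = metric, p = 0.1, mode = "cells", cells = ids,
                   cutoff = NA_real_, n_eligible = 40), class = "hotspot_set")
  }
  same <- overlap_summary(list(mk("a", cells$cell_id[1:5]),
                               mk("b", cells$cell_id[1:5])), cells, mat)
  expect_equal(same$pairwise$jaccard_pct, 100)
  expect_equal(same$per_n$n_cells, c(0, 5))

  disj <- overlap_summary(list(mk("a", cells$cell_id[1:5]),
                               mk("b", cells$cell_id[6:10])), cells, mat)
  expect_equal(disj$pairwise$jaccard_pct, 0)
  expect_equal(disj$union$n_cells, 10)
  expect_equal(disj$per_n$n_cells, c(10, 0))
})

test_that("distinct species are those covered by exactly one metric's set", {
  cells <- grid_fixture(1, 3)
  mat <- matrix(c(1L, 0L, 0L,
                  0L, 1L, 0L,
                  0L, 0L, 1L), nrow = 3, byrow = TRUE,
                dimnames = list(c("only_a", "shared", "only_b"), cells$cell_id))
  mat["shared", ] <- 1L
  mk <- function(metric, ids) {
    structure(list(metric = metric, p = 0.1, mode = "cells", cells = ids,
                   cutoff = NA_real_, n_eligible = 3), class = "hotspot_set")
  }
  ov <- overlap_summary(list(mk("a", "c1_1"), mk("b", "c1_3")), cells, mat)
  expect_equal(ov$distinct_species$a, "only_a")
  expect_equal(ov$distinct_species$b, "only_b")
  expect_equal(ov$species$union_count, 3)
})

test_that("region labeling follows queen vs rook adjacency semantics", {
  cells <- grid_fixture(10, 10)
  # two cells sharing an edge
  r1 <- label_regions(c("c1_1", "c1_2"), cells)
  expect_equal(nrow(r1$regions), 1)
  # diagonal neighbours: one region under queen, two under rook
  diag_cells <- c("c3_3", "c4_4")
  expect_equal(nrow(label_regions(diag_cells, cells, "queen")$regions), 1)
  expect_equal(nrow(label_regions(diag_cells, cells, "rook")$regions), 2)
  # 3x3 block plus a far singleton: sizes 9 and 1
  block <- as.vector(outer(6:8, 6:8, function(r, c) sprintf("c%d_%d", r, c)))
  rr <- label_regions(c(block, "c1_10"), cells)
  expect_equal(sort(rr$regions$n_cells), c(1, 9))
  expect_equal(rr$regions$n_cells[1], 9)  # region ids ordered by size
  # coordinates are required
  cells_nc <- cells
  cells_nc$row <- NA_integer_
  expect_error(label_regions("c1_1", cells_nc), "coordinates")
})

test_that("region taxon ratios match hand counts", {
  cells <- grid_fixture(2, 2)
  sp <- sprintf("sp%02d", 1:10)
  mat <- matrix(0L, 10, 4, dimnames = list(sp, cells$cell_id))
  mat[, "c1_1"] <- 1L
  taxonomy <- data.frame(species_id = sp,
                         genus = rep(paste0("g", 1:5), each = 2),
                         family = rep(c("f1", "f2"), each = 5))
  rt <- region_taxon_ratios("c1_1", mat, taxonomy)
  expect_equal(rt$species_genus_ratio, 2)
  expect_equal(rt$species_family_ratio, 5)
  # single species: both ratios 1
  rt1 <- region_taxon_ratios("c1_1", mat[1, , drop = FALSE], taxonomy)
  expect_equal(rt1$species_genus_ratio, 1)
  expect_equal(rt1$species_family_ratio, 1)
  expect_error(region_taxon_ratios("c1_1", mat, taxonomy[-1, ]), "sp01")
})
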