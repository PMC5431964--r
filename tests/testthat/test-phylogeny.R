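test_that("Newick round-trip preserves topology, labels and lengths", {
  txts <- c("((A:1,B:1):1,C:2);",      # resolved
            "(A:1,B:1,C:1);",          # polytomy kept as-is
            "(A:1);")                  # single leaf
  for (txt in txts) {
    tr <- read_newick(text = txt)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    back <- read_newick(path)
    expect_identical(back$tip.label, tr$tip.label)
    expect_identical(back$Nnode, tr$Nnode)
    expect_lt(max(abs(back$edge.length - tr$edge.length)), 1e-9)
  }
  tr <- read_newick(text = "(A:1,B:1,C:1);")
  expect_equal(sum(tr$edge[, 1L] == length(tr$tip.label) + 1L), 3L)
})

test_that("malformed Newick input is rejected", {
  expect_error(read_newick(text = "((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_newick(text = "((A,B);"))
})

test_that("faith_pd matches hand-worked values on the 3-taxon tree", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(faith_pd(tr, c("A", "B")), 3.0)
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5.0)
  expect_equal(faith_pd(tr, "A"), 2.0)        # rooted: root-path length
  expect_equal(faith_pd(tr, "A", rooted = FALSE), 0)
  expect_equal(faith_pd(tr, c("A", "B"), rooted = FALSE), 2.0)
  expect_error(faith_pd(tr, character(0)), "non-empty")
  expect_error(faith_pd(tr, "Z"), "not in tree")
})

test_that("faith_pd equals the path-enumeration oracle over all 255 subsets of an 8-leaf tree", {
  set.seed(11)
  tr <- ape::rcoal(8)
  tips <- tr$tip.label
  for (mask in 1:255) {
    taxa <- tips[as.logical(bitwAnd(mask, 2^(0:7)))]
    expect_equal(faith_pd(tr, taxa), oracle_pd(tr, taxa), tolerance = 1e-12)
  }
})

test_that("faith_pd is monotone under taxon addition and totals the tree", {
  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::rtree(10)
    taxa <- sample(tr$tip.label, 4)
    base <- faith_pd(tr, taxa)
    for (x in setdiff(tr$tip.label, taxa)) {
      expect_gte(faith_pd(tr, c(taxa, x)), base)
    }
    expect_equal(faith_pd(tr, tr$tip.label), sum(tr$edge.length))
  }
})

test_that("faith_pd agrees with picante's independent implementation", {
  skip_if_not_installed("picante")
  set.seed(3)
  tr <- ape::rcoal(12)
  comm <- matrix(as.integer(runif(3 * 12) < 0.4), nrow = 3,
                 dimnames = list(paste0("cell", 1:3), tr$tip.label))
  comm[1, 1] <- 1L  # avoid empty communities
  ours <- vapply(1:3, function(i) {
    taxa <- colnames(comm)[comm[i, ] > 0]
    if (length(taxa) == 0) return(NA_real_)
    faith_pd(tr, taxa)
  }, numeric(1L))
  ref <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("clade_ranges matches the from-scratch union oracle and is monotone rootward", {
  set.seed(21)
  for (rep in 1:5) {
    inst <- random_instance(10, 20)
    cr <- clade_ranges(inst$tree, inst$mat)
    for (i in seq_len(nrow(cr))) {
      e <- which(inst$tree$edge[, 1L] == cr$parent[i] &
                 inst$tree$edge[, 2L] == cr$child[i])
      expect_equal(cr$clade_range[i], oracle_clade_range(inst$tree, inst$mat, e))
    }
    # monotone non-decreasing from any branch toward the root
    by_child <- stats::setNames(cr$clade_range, cr$child)
    for (i in seq_len(nrow(cr))) {
      p <- as.character(cr$parent[i])
      if (p %in% names(by_child)) {
        expect_gte(by_child[[p]], cr$clade_range[i])
      }
    }
  }
})

test_that("leaf and sister-pair clade ranges follow the set-union definition", {
  wx <- worked_example()
  cr <- clade_ranges(wx$tree, wx$mat)
  ntip <- 3L
  leafB <- cr$clade_range[cr$child == match("B", wx$tree$tip.label)]
  expect_equal(leafB, 2)                      # R_c of a leaf = species range
  inner <- cr$clade_range[cr$child > ntip + 1L]
  expect_equal(inner, 2)                      # union of {c1} and {c1,c2}
})

test_that("bladj_smooth spaces unconstrained chain nodes evenly", {
  # root(12) -> N1 -> leaf(0): N1 gets 6
  sm <- bladj_smooth(chain_tree(1), data.frame(node_label = "R", age = 12))
  expect_equal(sort(attr(sm, "node_ages")), c(0, 6, 12))
  expect_equal(sm$edge.length, c(6, 6))

  # root(12) -> N1 -> N2 -> leaf(0): thirds, ages 8 and 4
  sm2 <- bladj_smooth(chain_tree(2), data.frame(node_label = "R", age = 12))
  expect_equal(sort(attr(sm2, "node_ages")), c(0, 4, 8, 12))
  expect_equal(sm2$edge.length, c(4, 4, 4))
})

test_that("bladj_smooth honours fully fixed ages and rejects inconsistencies", {
  tr <- read_newick(text = "((A:1,B:1)X:1,C:1)R;")
  sm <- bladj_smooth(tr, data.frame(node_label = c("R", "X"), age = c(10, 4)))
  # all internal nodes fixed: branch lengths are exact age differences
  expect_equal(sort(sm$edge.length), c(4, 4, 6, 10))
  expect_error(
    bladj_smooth(tr, data.frame(node_label = c("R", "X"), age = c(3, 9))),
    "exceeds"
  )
  expect_error(bladj_smooth(tr, data.frame(node_label = "X", age = 4)), "root")
})

test_that("bladj_smooth output is ultrametric when leaves are extant", {
  set.seed(9)
  tr <- ape::rtree(12)
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  sm <- bladj_smooth(tr, data.frame(node_label = "n1", age = 50))
  expect_true(ape::is.ultrametric(sm, tol = 1e-8))
  ages <- attr(sm, "node_ages")
  # age consistency: parent strictly older wherever the branch has length
  len <- sm$edge.length
  expect_true(all(ages[sm$edge[, 1L]] - ages[sm$edge[, 2L]] >= -1e-9))
  expect_true(all((ages[sm$edge[, 1L]] > ages[sm$edge[, 2L]])[len > 0]))
})
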