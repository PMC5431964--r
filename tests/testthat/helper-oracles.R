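# Independent brute-force oracles: explicit root-path enumeration and
# from-scratch set unions, deliberately sharing no code with the package's
# single-sweep implementations.

oracle_root_path_edges <- function(tree, tip_label) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  v <- match(tip_label, tree$tip.label)
  edges <- integer(0)
  while (v != root) {
    e <- which(tree$edge[, 2L] == v)
    edges <- c(edges, e)
    v <- tree$edge[e, 1L]
  }
  edges
}

oracle_pd <- function(tree, taxa) {
  ed <- unique(unlist(lapply(taxa, oracle_root_path_edges, tree = tree)))
  sum(tree$edge.length[ed])
}

oracle_descendant_tips <- function(tree, edge_i) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[edge_i, 2L]
  if (child <= ntip) return(tree$tip.label[child])
  queue <- child
  tips <- character(0)
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    ch <- tree$edge[tree$edge[, 1L] == v, 2L]
    tips <- c(tips, tree$tip.label[ch[ch <= ntip]])
    queue <- c(queue, ch[ch > ntip])
  }
  tips
}

oracle_clade_range <- function(tree, mat, edge_i) {
  tips <- intersect(oracle_descendant_tips(tree, edge_i), rownames(mat))
  if (length(tips) == 0L) return(0L)
  sum(colSums(mat[tips, , drop = FALSE]) > 0)
}

oracle_pe_cell <- function(tree, mat, cell) {
  taxa <- rownames(mat)[mat[, cell] > 0]
  if (length(taxa) == 0L) return(0)
  ed <- unique(unlist(lapply(taxa, oracle_root_path_edges, tree = tree)))
  sum(vapply(ed, function(e) {
    tree$edge.length[e] / oracle_clade_range(tree, mat, e)
  }, numeric(1L)))
}

oracle_cwe_cell <- function(mat, cell) {
  taxa <- rownames(mat)[mat[, cell] > 0]
  if (length(taxa) == 0L) return(NA_real_)
  rj <- vapply(taxa, function(s) sum(mat[s, ] > 0), numeric(1L))
  sum(1 / rj) / length(taxa) * 100
}

# Random small instance: an independent random tree (ape::rtree, not the
# package generator) and a random binary matrix with every species in >= 1
# cell and cells possibly empty.
random_instance <- function(n_species, n_cells, p_occ = 0.3) {
  tree <- ape::rtree(n_species)
  tree$tip.label <- paste0("s", seq_len(n_species))
  mat <- matrix(as.integer(stats::runif(n_species * n_cells) < p_occ),
                nrow = n_species,
                dimnames = list(tree$tip.label, paste0("x", seq_len(n_cells))))
  empty_sp <- rowSums(mat) == 0
  mat[cbind(which(empty_sp), sample.int(n_cells, sum(empty_sp), replace = TRUE))] <- 1L
  list(tree = tree, mat = mat)
}

# The analytically worked 3-taxon example: ((A:1,B:1):1,C:2); with
# A in c1, B in c1+c2, C in c2.
worked_example <- function() {
  tree <- read_newick(text = "((A:1,B:1):1,C:2);")
  mat <- matrix(c(1L, 0L, 1L, 1L, 0L, 1L), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("c1", "c2")))
  list(tree = tree, mat = mat)
}

# Chain tree: root "R" -> k unlabeled-age internal nodes "N1".."Nk" -> one
# leaf "A", unit branch lengths. Built by hand because ape's Newick reader
# scrambles node labels on singleton chains.
chain_tree <- function(k) {
  nnode <- k + 1L
  ids <- seq(2L, 1L + nnode)
  edge <- cbind(ids, c(ids[-1L], 1L))
  storage.mode(edge) <- "integer"
  structure(list(edge = edge, edge.length = rep(1, nrow(edge)),
                 Nnode = nnode, tip.label = "A",
                 node.label = c("R", if (k > 0) paste0("N", seq_len(k)))),
            class = "phylo")
}

# Small grid fixture: n_rows x n_cols cell table with uniform areas.
grid_fixture <- function(n_rows, n_cols, land_area = 2500, reserve_area = 0) {
  rc <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  data.frame(cell_id = sprintf("c%d_%d", rc$row, rc$col),
             row = rc$row, col = rc$col,
             land_area = land_area, reserve_area = reserve_area)
}
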