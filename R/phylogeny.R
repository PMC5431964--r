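#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that additionally validates the
#' structural assumptions of the diversity metrics: a single rooted tree,
#' unique tip labels, and non-negative branch lengths. Polytomies are
#' permitted and kept as-is (supertrees assembled from taxonomic backbones
#' are polytomy-rich).
#'
#' @param path path to a Newick file, or a Newick string via `text`.
#' @param text optional Newick string, used instead of `path`.
#' @return an object of class `phylo`.
#' @seealso [write_newick()]
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tree)) stop("failed to parse Newick input", call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    stop("input contains multiple trees; exactly one is expected", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  tree
}

#' Write a phylogeny to a Newick file
#'
#' Round-tripping through [read_newick()] preserves topology, labels and
#' branch lengths to better than 1e-9 relative precision.
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Postorder edge matrix plus a node-by-item presence matrix seeded at the
# tips; each internal node's row becomes the OR over its children. This one
# sweep underlies PD, PE and clade ranges.
node_presence <- function(tree, tip_presence) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # reorder.phylo keeps node numbering; only edge order changes
  po <- if (ntip > 1L) ape::reorder.phylo(tree, "postorder") else tree
  pres <- matrix(FALSE, nrow = nnode, ncol = ncol(tip_presence))
  pres[seq_len(ntip), ] <- tip_presence[tree$tip.label, , drop = FALSE]
  edges <- po$edge
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]
    ch <- edges[i, 2L]
    pres[p, ] <- pres[p, ] | pres[ch, ]
  }
  list(edge = edges, edge.length = po$edge.length, presence = pres, ntip = ntip)
}

#' Faith's phylogenetic diversity of a taxon set
#'
#' Sum of the branch lengths spanned by a set of taxa. Under the default
#' rooted convention the spanning paths run from each taxon to the root, so
#' the stem above the taxa's most recent common ancestor is included and the
#' PD of a single taxon equals its root-path length. This convention makes
#' the identity `sum over cells of PE == faith_pd(all present taxa)` exact.
#' `rooted = FALSE` gives the classical unrooted variant (branches on paths
#' between the taxa only; 0 for a single taxon).
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels, non-empty.
#' @param rooted include the root-to-MRCA stem (default `TRUE`).
#' @return a single non-negative number.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B"))        # 3
#' faith_pd(tr, c("A", "B", "C"))   # 5, the total branch length
#' @export
faith_pd <- function(tree, taxa, rooted = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("`taxa` must be non-empty", call. = FALSE)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  tp <- matrix(tree$tip.label %in% taxa, ncol = 1L,
               dimnames = list(tree$tip.label, NULL))
  np <- node_presence(tree, tp)
  child_pres <- np$presence[np$edge[, 2L], 1L]
  if (rooted) {
    sum(np$edge.length[child_pres])
  } else {
    # branches strictly inside the spanning tree between taxa: subtree below
    # the edge holds at least one but not all of the taxa
    counts <- integer(nrow(np$presence))
    counts[seq_len(np$ntip)] <- as.integer(tp[, 1L])
    for (i in seq_len(nrow(np$edge))) {
      counts[np$edge[i, 1L]] <- counts[np$edge[i, 1L]] + counts[np$edge[i, 2L]]
    }
    k <- length(taxa)
    inside <- counts[np$edge[, 2L]] > 0L & counts[np$edge[, 2L]] < k
    sum(np$edge.length[inside])
  }
}

#' Per-branch clade ranges
#'
#' For every branch of the tree, the clade range is the number of grid cells
#' occupied by at least one descendant taxon, counting each cell once however
#' many descendants share it. Branches whose descendants are all absent from
#' the matrix are excluded from the index.
#'
#' @param tree a `phylo` object whose tips match the matrix rows (see
#'   [align_taxa()]).
#' @param matrix binary occurrence matrix (species x cells) as produced by
#'   [load_occurrences()].
#' @return a data frame with one row per branch: `parent`, `child` (ape node
#'   ids), `edge_length`, and `clade_range`.
#' @export
clade_ranges <- function(tree, matrix) {
  check_aligned(tree, matrix)
  np <- node_presence(tree, matrix > 0)
  rc <- rowSums(np$presence[np$edge[, 2L], , drop = FALSE])
  out <- data.frame(parent = np$edge[, 1L], child = np$edge[, 2L],
                    edge_length = np$edge.length, clade_range = rc)
  out[out$clade_range > 0L, , drop = FALSE]
}

check_aligned <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), is.matrix(matrix))
  if (!setequal(rownames(matrix), tree$tip.label)) {
    stop("matrix species and tree tips differ; run align_taxa() first",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' BLADJ-style branch-length age smoothing
#'
#' Assigns ages to internal nodes that lack a fixed age by even
#' interpolation: along each root-to-leaf path, unconstrained nodes lying
#' between two consecutive age-constrained nodes are spaced at equal age
#' steps. Branch lengths are then recomputed as parent age minus child age.
#' Leaves default to age 0 (extant taxa); the root age must be fixed.
#'
#' When the tree is not a chain, a node can sit on several root-to-leaf
#' paths; interpolation runs over paths in a deterministic order (tips in
#' cladewise appearance order) and a node's age is fixed by the first path
#' that assigns it. This matches the even-placement intent of the Phylocom
#' BLADJ algorithm without claiming bit-compatibility.
#'
#' @param tree a `phylo` object with internal node labels for every node
#'   named in `ages`.
#' @param ages a data frame with columns `node_label` and `age` giving fixed
#'   ages (time before present, same units as the desired branch lengths).
#'   Must include the root. Leaf labels may be included to fix non-zero tip
#'   ages.
#' @return a `phylo` object with recomputed `edge.length`; node ages are
#'   attached as attribute `"node_ages"` (ordered by ape node id).
#' @examples
#' tr <- read_newick(text = "((A:1)X:1)R;")   # chain R -> X -> A
#' sm <- bladj_smooth(tr, data.frame(node_label = "R", age = 12))
#' attr(sm, "node_ages")   # A = 0, X = 6, R = 12
#' @export
bladj_smooth <- function(tree, ages) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(ages))
  if (!all(c("node_label", "age") %in% names(ages))) {
    stop("`ages` needs columns node_label and age", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode)
              else tree$node.label)

  age <- rep(NA_real_, nnode)
  age[seq_len(ntip)] <- 0
  fixed <- c(rep(TRUE, ntip), rep(FALSE, tree$Nnode))
  idx <- match(ages$node_label, labels)
  if (anyNA(idx)) {
    stop("age constraints reference unknown node label(s): ",
         paste(ages$node_label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  age[idx] <- ages$age
  fixed[idx] <- TRUE
  if (!fixed[root] || is.na(age[root])) {
    stop("the root age must be fixed", call. = FALSE)
  }

  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]

  # consistency: every fixed node younger than its nearest fixed ancestor
  for (v in which(fixed)) {
    if (v == root) next
    a <- parent[v]
    while (a != root && !fixed[a]) a <- parent[a]
    if (fixed[a] && age[v] > age[a] + 1e-12) {
      stop("fixed age of node '", labels[v] %||% v,
           "' exceeds the age of its nearest fixed ancestor", call. = FALSE)
    }
  }

  # tips in cladewise appearance order for a deterministic traversal
  cw <- if (ntip > 1L) ape::reorder.phylo(tree, "cladewise") else tree
  tip_order <- cw$edge[cw$edge[, 2L] <= ntip, 2L]
  if (length(tip_order) == 0L) tip_order <- seq_len(ntip)

  assigned <- fixed
  for (tip in tip_order) {
    # root-to-tip node path
    path <- tip
    v <- tip
    while (v != root) {
      v <- parent[v]
      path <- c(v, path)
    }
    anchors <- which(assigned[path])
    for (k in seq_len(length(anchors) - 1L)) {
      i <- anchors[k]
      j <- anchors[k + 1L]
      if (j - i <= 1L) next
      a_top <- age[path[i]]
      a_bot <- age[path[j]]
      steps <- j - i
      for (m in seq_len(steps - 1L)) {
        node <- path[i + m]
        if (!assigned[node]) {
          age[node] <- a_top - m * (a_top - a_bot) / steps
          assigned[node] <- TRUE
        }
      }
    }
  }
  if (anyNA(age)) stop("internal error: unassigned node ages remain", call. = FALSE)

  len <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  if (any(len < -1e-9)) {
    stop("age assignment produced a negative branch length; check constraints",
         call. = FALSE)
  }
  len[len < 0] <- 0
  out <- tree
  out$edge.length <- len
  attr(out, "node_ages") <- age
  out
}
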