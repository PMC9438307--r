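#' Read a tree from a Newick file
#'
#' Uses [ape::read.tree()]. Internal node labels that are numeric and within
#' \[0, 100\] are interpreted downstream as bootstrap support percentages (the
#' common IQ-TREE dialect); non-numeric labels are preserved but ignored by
#' support-based operations.
#'
#' @param path path to a Newick file (single tree).
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in '", path, "'")
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Check that a rooted tree is ultrametric
#'
#' All root-to-tip path lengths must agree within a relative tolerance.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tol relative tolerance (default 1e-6).
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- node_depths(tree)[seq_len(length(tree$tip.label))]
  (max(depths) - min(depths)) <= tol * max(depths, 1e-300)
}

#' Validate a time-calibrated species tree
#'
#' Checks that the tree is rooted, binary, has non-negative branch lengths,
#' and (optionally) is ultrametric. Polytomous species trees are rejected:
#' all downstream reconciliation assumes a binary chronogram.
#'
#' @param tree a `phylo` object.
#' @param ultrametric require ultrametricity (default TRUE).
#' @return `tree`, invisibly; errors otherwise.
#' @export
validate_time_tree <- function(tree, ultrametric = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be binary (no polytomies)")
  if (is.null(tree$edge.length)) stop("species tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (ultrametric && !is_ultrametric_tree(tree)) stop("tree is not ultrametric")
  invisible(tree)
}

# --- internal tree helpers ---------------------------------------------------

# depth (distance from root) of every node, indexed by ape node id
node_depths <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  depth <- numeric(n_node)
  root <- length(tree$tip.label) + 1L
  # edges in preorder
  ord <- reorder_edges_preorder(tree)
  for (k in ord) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    depth[c] <- depth[p] + tree$edge.length[k]
  }
  depth
}

reorder_edges_preorder <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  ord <- integer(0)
  stack <- as.integer(root)
  while (length(stack)) {
    node <- stack[length(stack)]; stack <- stack[-length(stack)]
    ke <- children[[as.character(node)]]
    if (!is.null(ke)) {
      ord <- c(ord, ke)
      stack <- c(stack, tree$edge[ke, 2])
    }
  }
  ord
}

# children list: for each node id, the edge rows leaving it
edges_by_parent <- function(tree) {
  split(seq_len(nrow(tree$edge)), factor(tree$edge[, 1],
        levels = seq_len(length(tree$tip.label) + tree$Nnode)))
}

# parent edge row for each node (NA for root)
parent_edge_of <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  pe <- rep(NA_integer_, n_node)
  pe[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  pe
}

#' Map gene-tree leaves to species
#'
#' Leaf labels follow the `species|copy` convention: everything before the
#' first `|` is the species name. An explicit mapping overrides this.
#'
#' @param gene_tree a `phylo` gene tree.
#' @param map optional named character vector (leaf label -> species).
#' @return character vector of species, one per leaf, named by leaf label.
#' @export
leaf_species <- function(gene_tree, map = NULL) {
  labs <- gene_tree$tip.label
  if (!is.null(map)) {
    sp <- unname(map[labs])
    if (anyNA(sp)) stop("unmapped gene-tree leaves: ",
                        paste(labs[is.na(sp)], collapse = ", "))
  } else {
    sp <- sub("\\|.*$", "", labs)
  }
  setNames(sp, labs)
}

# numeric support values from node labels (NA where absent/non-numeric)
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!is.na(sup) & (sup < 0 | sup > 100)] <- NA
  sup
}
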