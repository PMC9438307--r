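# Gene-tree / species-tree reconciliation under the duplication-loss
# parsimony model (LCA mapping), with support-based collapsing, exhaustive
# rooting, and exhaustive polytomy resolution at small sizes.

#' Collapse weakly supported gene-tree nodes into polytomies
#'
#' Internal nodes whose (numeric) support label is strictly below `threshold`
#' are contracted into their parent. Nodes with no support value or a
#' non-numeric label are kept.
#'
#' @param gene_tree a `phylo` with support values as internal node labels.
#' @param threshold collapse threshold in percent (default 90; `< threshold`
#'   collapses).
#' @return a `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(gene_tree, threshold = 90) {
  n_tip <- length(gene_tree$tip.label)
  if (n_tip < 3 || gene_tree$Nnode < 2) return(gene_tree)
  sup <- node_supports(gene_tree)
  ebp <- edges_by_parent(gene_tree)
  has_len <- !is.null(gene_tree$edge.length)
  root <- n_tip + 1L
  collapsible <- function(node)
    node > n_tip && node != root && !is.na(sup[node - n_tip]) &&
      sup[node - n_tip] < threshold
  frag <- function(node) {
    if (node <= n_tip) return(gene_tree$tip.label[node])
    lab <- if (!is.null(gene_tree$node.label)) gene_tree$node.label[node - n_tip] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(unlist(lapply(ebp[[node]], expand_child)), collapse = ","),
           ")", lab)
  }
  expand_child <- function(ke) {
    ch <- gene_tree$edge[ke, 2]
    if (collapsible(ch)) return(unlist(lapply(ebp[[ch]], expand_child)))
    piece <- frag(ch)
    if (has_len) piece <- paste0(piece, ":", sprintf("%.8f", gene_tree$edge.length[ke]))
    piece
  }
  ape::read.tree(text = paste0(frag(root), ";"))
}

# --- species-tree helper bundle ---------------------------------------------

species_index <- function(species_tree) {
  n_tip <- length(species_tree$tip.label)
  n_node <- n_tip + species_tree$Nnode
  parent <- rep(NA_integer_, n_node)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  depth <- integer(n_node)
  for (k in reorder_edges_preorder(species_tree)) {
    depth[species_tree$edge[k, 2]] <- depth[species_tree$edge[k, 1]] + 1L
  }
  children <- vector("list", n_node)
  for (k in seq_len(nrow(species_tree$edge)))
    children[[species_tree$edge[k, 1]]] <-
      c(children[[species_tree$edge[k, 1]]], species_tree$edge[k, 2])
  list(tree = species_tree, n_tip = n_tip, root = n_tip + 1L,
       parent = parent, depth = depth, children = children)
}

species_lca <- function(si, a, b) {
  while (si$depth[a] > si$depth[b]) a <- si$parent[a]
  while (si$depth[b] > si$depth[a]) b <- si$parent[b]
  while (a != b) { a <- si$parent[a]; b <- si$parent[b] }
  a
}

#' LCA reconciliation of a rooted binary gene tree with a species tree
#'
#' Maps every gene-tree node to the most recent common ancestor (in the
#' species tree) of its descendant species; a node whose child maps to the
#' same species node is a duplication. Losses are placed on explicit species
#' branches by the path rule: a gene lineage passing a speciation node
#' without splitting implies a loss on the branch to that node's other
#' child. Duplications are attributed to the species branch above their
#' mapped node (the synthetic root stem for root-mapped duplications).
#'
#' @param gene_tree rooted binary `phylo`; leaf labels `species|copy` (or use
#'   `map`).
#' @param species_tree rooted binary `phylo`.
#' @param map optional named vector, gene leaf -> species.
#' @return object of class `reconciliation`: `M` (per gene node, species node
#'   id), `events` (per internal gene node), `duplications`, `losses`
#'   (totals), `gains_by_branch` / `losses_by_branch` (named by the species
#'   branch's child node id; the root id denotes the stem), `root_mapping`.
#' @export
lca_reconcile <- function(gene_tree, species_tree, map = NULL) {
  si <- species_index(species_tree)
  n_tip <- length(gene_tree$tip.label)
  if (!ape::is.binary(gene_tree) || !ape::is.rooted(gene_tree))
    stop("gene tree must be rooted and binary for LCA reconciliation")
  sp <- leaf_species(gene_tree, map)
  sp_id <- match(sp, species_tree$tip.label)
  if (anyNA(sp_id))
    stop("gene leaves map to species absent from the species tree: ",
         paste(unique(sp[is.na(sp_id)]), collapse = ", "))
  n_node <- n_tip + gene_tree$Nnode
  M <- integer(n_node)
  M[seq_len(n_tip)] <- sp_id
  post <- rev(reorder_edges_preorder(gene_tree))
  kids <- vector("list", n_node)
  for (k in seq_len(nrow(gene_tree$edge)))
    kids[[gene_tree$edge[k, 1]]] <- c(kids[[gene_tree$edge[k, 1]]],
                                      gene_tree$edge[k, 2])
  for (k in post) {
    p <- gene_tree$edge[k, 1]
    cc <- kids[[p]]
    if (M[p] == 0L) M[p] <- Reduce(function(a, b) species_lca(si, a, b), M[cc])
  }
  events <- rep(NA_character_, n_node)
  for (v in (n_tip + 1L):n_node) {
    events[v] <- if (any(M[kids[[v]]] == M[v])) "duplication" else "speciation"
  }
  n_sp_node <- si$n_tip + species_tree$Nnode
  gains <- integer(n_sp_node); losses <- integer(n_sp_node)
  for (v in (n_tip + 1L):n_node) {
    if (events[v] == "duplication") gains[M[v]] <- gains[M[v]] + 1L
  }
  # loss placement along each gene edge
  for (k in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[k, 1]; v <- gene_tree$edge[k, 2]
    x <- M[v]
    if (x == M[u]) next
    repeat {
      p <- si$parent[x]
      if (p == M[u]) {
        if (events[u] == "duplication") {
          oc <- setdiff(si$children[[p]], x)
          losses[oc] <- losses[oc] + 1L
        }
        break
      }
      oc <- setdiff(si$children[[p]], x)
      losses[oc] <- losses[oc] + 1L
      x <- p
    }
  }
  structure(list(
    gene_tree = gene_tree, species_tree = species_tree, M = M, events = events,
    duplications = sum(events == "duplication", na.rm = TRUE),
    losses = sum(losses),
    gains_by_branch = setNames(gains, as.character(seq_len(n_sp_node))),
    losses_by_branch = setNames(losses, as.character(seq_len(n_sp_node))),
    root_mapping = M[n_tip + 1L],
    cost = sum(events == "duplication", na.rm = TRUE) + sum(losses)),
    class = "reconciliation")
}

# --- rooting and polytomy resolution ----------------------------------------

# nested-list topology helpers: a "shape" is a tip label (character) or an
# unnamed list of >= 2 shapes
shape_to_newick <- function(s) {
  if (is.character(s)) return(s)
  paste0("(", paste(vapply(s, shape_to_newick, ""), collapse = ","), ")")
}

# all rooted binary shapes over a list of child shapes ((2k-3)!! shapes, each
# exactly once). Children are atomic: the enumeration works on index leaves
# and substitutes the child shapes afterwards, so it can never rearrange the
# inside of an existing subtree.
all_binary_shapes <- function(items) {
  substitute_items <- function(s) {
    if (!is.list(s)) return(items[[s]])
    lapply(s, substitute_items)
  }
  lapply(all_index_shapes(length(items)), substitute_items)
}

all_index_shapes <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(list(1L, 2L)))
  prev <- all_index_shapes(k - 1L)
  out <- list()
  for (s in prev) {
    for (ins in insert_leaf(s, k)) out[[length(out) + 1L]] <- ins
  }
  out
}

# insert leaf index on every edge of an index shape (including above the root)
insert_leaf <- function(s, leaf) {
  out <- list(list(leaf, s))
  if (is.list(s)) {
    for (i in seq_along(s)) {
      for (sub in insert_leaf(s[[i]], leaf)) {
        s2 <- s
        s2[[i]] <- sub
        out[[length(out) + 1L]] <- s2
      }
    }
  }
  out
}

double_factorial <- function(k) if (k <= 1) 1 else prod(seq(k, 1, by = -2))

# convert a phylo (rooted or not, possibly multifurcating) into an
# undirected graph; degree-2 nodes (a rooted tree's root) are suppressed
phylo_graph <- function(tree) {
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_tip + tree$Nnode)
  for (v in which(deg == 2)) {
    if (v <= n_tip) next
    inc <- which(edges[, 1] == v | edges[, 2] == v)
    if (length(inc) != 2) next
    other <- vapply(inc, function(k) setdiff(edges[k, ], v), 1)
    edges <- edges[-inc, , drop = FALSE]
    edges <- rbind(edges, other)
  }
  list(edges = unname(edges), n_tip = n_tip, labels = tree$tip.label)
}

graph_neighbors <- function(g) {
  n <- max(g$edges)
  nb <- vector("list", n)
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges[k, 1]; b <- g$edges[k, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

# shape of the subtree seen from `node` arriving from `from`
graph_subshape <- function(g, nb, node, from) {
  if (node <= g$n_tip) return(g$labels[node])
  kids <- setdiff(nb[[node]], from)
  lapply(kids, function(k) graph_subshape(g, nb, k, node))
}

# greedy resolution of multifurcations: repeatedly join the pair of children
# whose species LCA is deepest
greedy_resolve <- function(shape, si, sp_of_label) {
  resolve <- function(s) {
    if (is.character(s)) return(s)
    s <- lapply(s, resolve)
    while (length(s) > 2) {
      maps <- vapply(s, function(x) shape_species_map(x, si, sp_of_label), 1L)
      bestd <- -1L; bi <- 1L; bj <- 2L
      for (i in seq_len(length(s) - 1)) for (j in (i + 1):length(s)) {
        d <- si$depth[species_lca(si, maps[i], maps[j])]
        if (d > bestd) { bestd <- d; bi <- i; bj <- j }
      }
      joined <- list(s[[bi]], s[[bj]])
      s <- c(s[-c(bi, bj)], list(joined))
    }
    s
  }
  resolve(shape)
}

shape_species_map <- function(s, si, sp_of_label) {
  if (is.character(s)) return(sp_of_label[[s]])
  Reduce(function(a, b) species_lca(si, a, b),
         vapply(s, shape_species_map, 1L, si = si, sp_of_label = sp_of_label))
}

# all resolutions of every polytomy in `shape` (cartesian), or NULL if the
# total count exceeds `cap`
all_resolutions <- function(shape, cap) {
  count <- function(s) {
    if (is.character(s)) return(1)
    prod(vapply(s, count, 1)) * double_factorial(2 * length(s) - 3)
  }
  if (count(shape) > cap) return(NULL)
  rec <- function(s) {
    if (is.character(s)) return(list(s))
    child_sets <- lapply(s, rec)
    combos <- list(list())
    for (cs in child_sets) {
      combos <- unlist(lapply(combos, function(pref)
        lapply(cs, function(x) c(pref, list(x)))), recursive = FALSE)
    }
    unlist(lapply(combos, function(kids) all_binary_shapes(kids)),
           recursive = FALSE)
  }
  rec(shape)
}

#' Root and reconcile a gene tree by duplication-loss minimisation
#'
#' Considers every edge of the (unrooted view of the) gene tree as a root
#' position and, for multifurcating trees, every binary resolution of each
#' polytomy (exhaustively while the total number of resolutions is at most
#' `resolution_cap`, which covers polytomies of up to 7 children; larger
#' inputs fall back to a greedy deepest-LCA resolution with a warning).
#' Returns the minimum-cost reconciliation; ties are broken by duplication
#' count, then loss count, then root-edge index, then resolution index.
#'
#' @param gene_tree `phylo`, rooted or unrooted, possibly multifurcating,
#'   with at least 3 leaves.
#' @param species_tree rooted binary `phylo`.
#' @param map optional named vector, gene leaf -> species.
#' @param resolution_cap maximum number of binary resolutions enumerated
#'   exhaustively (default 20000 > (2*7-3)!! = 10395).
#' @return a `reconciliation` (see [lca_reconcile()]).
#' @export
root_and_reconcile <- function(gene_tree, species_tree, map = NULL,
                               resolution_cap = 20000L) {
  if (length(gene_tree$tip.label) < 3)
    stop("root_and_reconcile needs >= 3 leaves")
  si <- species_index(species_tree)
  sp <- leaf_species(gene_tree, map)
  sp_of_label <- as.list(setNames(match(sp, species_tree$tip.label), names(sp)))
  if (anyNA(unlist(sp_of_label))) stop("unmapped gene-tree leaves")
  g <- phylo_graph(gene_tree)
  nb <- graph_neighbors(g)
  # candidate root positions: every edge, plus (for polytomies) every
  # internal node of degree >= 4 -- a root inside a resolved polytomy blob is
  # not on any original edge, but is covered by rooting "at" the node over
  # all binary arrangements of its neighbour subtrees
  rooted_shapes <- list()
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges[k, 1]; b <- g$edges[k, 2]
    rooted_shapes[[length(rooted_shapes) + 1L]] <-
      list(graph_subshape(g, nb, a, b), graph_subshape(g, nb, b, a))
  }
  for (v in seq_along(nb)) {
    if (v <= g$n_tip || length(nb[[v]]) < 4) next
    rooted_shapes[[length(rooted_shapes) + 1L]] <-
      lapply(nb[[v]], function(u) graph_subshape(g, nb, u, v))
  }
  best <- NULL
  best_key <- c(Inf, Inf, Inf, Inf)
  for (k in seq_along(rooted_shapes)) {
    rooted <- rooted_shapes[[k]]
    cands <- all_resolutions(rooted, resolution_cap)
    if (is.null(cands)) {
      warning("polytomies too large for exhaustive resolution; using greedy ",
              "deepest-LCA resolution")
      cands <- list(greedy_resolve(rooted, si, sp_of_label))
    }
    for (ci in seq_along(cands)) {
      tr <- ape::read.tree(text = paste0(shape_to_newick(cands[[ci]]), ";"))
      rec <- lca_reconcile(tr, species_tree, map)
      key <- c(rec$cost, rec$duplications, rec$losses, k * 1e6 + ci)
      if (is.null(best) ||
          key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2]) ||
          (key[1] == best_key[1] && key[2] == best_key[2] && key[3] < best_key[3])) {
        best <- rec; best_key <- key
      }
    }
  }
  best
}

#' Tabulate per-branch gene gains and losses for a family
#'
#' Aggregates a set of reconciliations (one per gene tree of the family)
#' into a per-species-branch event table. Each reconciliation contributes
#' one lineage origination on the branch above its root mapping (recorded in
#' the `origins` column; the synthetic root stem when the gene root maps to
#' the species root), duplications as gains `G`, and losses `L`. Ancestral
#' copy numbers satisfy `N_child = N_parent + G + origins - L` on every
#' branch; for gene trees whose root maps to the species root this is the
#' plain gain/loss bookkeeping identity.
#'
#' Singleton gene trees (a bare tip label, no reconciliation possible) can be
#' passed as character species names via `singletons`; each contributes an
#' origination above its species tip.
#'
#' @param reconciliations list of `reconciliation` objects sharing one
#'   species tree.
#' @param species_tree the shared species tree.
#' @param family family label for the output.
#' @param singletons character vector of species names of single-copy gene
#'   "trees".
#' @return a `branch_event_table` data.frame: `branch_child` (ape node id of
#'   the branch's child; the root id denotes the stem), `parent`, `t` (My; NA
#'   for the stem), `G`, `L`, `origins`, `N_parent`, `N_child`, `family`.
#' @export
tabulate_branch_events <- function(reconciliations, species_tree,
                                   family = "OR", singletons = character(0)) {
  si <- species_index(species_tree)
  n_node <- si$n_tip + species_tree$Nnode
  G <- integer(n_node); L <- integer(n_node); O <- integer(n_node)
  for (rec in reconciliations) {
    if (!identical(rec$species_tree$tip.label, species_tree$tip.label))
      stop("reconciliations must share the species tree")
    G <- G + as.integer(rec$gains_by_branch)
    L <- L + as.integer(rec$losses_by_branch)
    O[rec$root_mapping] <- O[rec$root_mapping] + 1L
  }
  for (s in singletons) {
    id <- match(s, species_tree$tip.label)
    if (is.na(id)) stop("singleton species not in tree: ", s)
    O[id] <- O[id] + 1L
  }
  # top-down copy numbers; entering count at the top of the stem is 0
  N <- integer(n_node)
  N[si$root] <- G[si$root] + O[si$root] - L[si$root]
  pe <- parent_edge_of(species_tree)
  for (k in reorder_edges_preorder(species_tree)) {
    p <- species_tree$edge[k, 1]; ch <- species_tree$edge[k, 2]
    N[ch] <- N[p] + G[ch] + O[ch] - L[ch]
  }
  if (any(N < 0)) stop("negative ancestral copy number; inconsistent input")
  ids <- c(si$root, setdiff(seq_len(n_node), si$root))
  parent <- si$parent[ids]
  t <- unname(ifelse(is.na(parent), NA_real_,
                     species_tree$edge.length[pe[ids]]))
  out <- data.frame(branch_child = ids, parent = parent, t = t,
                    G = G[ids], L = L[ids], origins = O[ids],
                    N_parent = ifelse(is.na(parent), 0L, N[parent]),
                    N_child = N[ids], family = family,
                    stringsAsFactors = FALSE)
  class(out) <- c("branch_event_table", "data.frame")
  out
}
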