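# Birth-death simulation of gene-family histories along a species tree.
#
# Each gene lineage evolves independently (linear birth-death process): along
# a species branch of length t with rate multiplier m, a lineage duplicates at
# rate b*m and dies at rate d*m (per gene per My); at speciation nodes every
# surviving lineage is copied into both daughter branches. The full genealogy
# is retained, so every simulated family comes with its true gene trees,
# per-branch event lists, and per-node copy numbers.

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) topology rescaled so that every root-to-tip path equals
#' `crown_age_my` -- a stand-in for a time-calibrated chronogram. A Yule
#' process, unlike a coalescent, does not concentrate vanishingly short
#' branches near the present, which matches the branch-length profile of
#' published chronograms.
#'
#' @param n_taxa number of species (>= 2).
#' @param crown_age_my root-to-tip depth in My.
#' @param seed RNG seed.
#' @return a rooted, binary, ultrametric `phylo`; tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_taxa, crown_age_my = 300, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  with_seed(seed, {
    tr <- if (n_taxa == 2) ape::read.tree(text = "(sp01:1,sp02:1);")
          else ape::rphylo(n_taxa, birth = 1, death = 0)
    tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
    depth <- max(node_depths(tr))
    tr$edge.length <- tr$edge.length * (crown_age_my / depth)
    tr$node.label <- NULL
    tr
  })
}

default_family_rates <- function() {
  data.frame(family = FAMILIES,
             b = c(0.0071, 0.0101, 0.0059, 0.0018),
             d = c(0.0071, 0.0079, 0.0069, 0.0047),
             root_count = c(40L, 20L, 15L, 8L),
             stringsAsFactors = FALSE)
}

#' Simulate one gene family's birth-death history along a species tree
#'
#' Exact next-event (Gillespie) simulation of a linear birth-death process per
#' gene lineage. Gains and losses are recorded per species-tree branch with
#' time stamps, per-node copy numbers are tracked, and the true genealogy of
#' every surviving root lineage is returned as a gene tree.
#'
#' @param tree rooted species tree (`phylo`, branch lengths in My).
#' @param b,d birth and death rates per gene per My (>= 0).
#' @param root_count copy number at the root (>= 0).
#' @param rate_multipliers optional per-branch rate multipliers, named by the
#'   ape id of each branch's child node; default all 1.
#' @param seed RNG seed.
#' @param family family label carried through to outputs.
#' @return an object of class `family_history`: fields `counts` (per ape node
#'   id), `events` (data.frame: `edge_child`, `type`, `time`, `lineage`,
#'   `root_lineage`), `gene_trees` (per surviving root lineage: a `phylo`, or
#'   a single tip label for singleton survivors), `tips` (data.frame of tip
#'   copies), plus the inputs.
#' @export
simulate_family_counts <- function(tree, b, d, root_count,
                                   rate_multipliers = NULL, seed = NULL,
                                   family = "OR") {
  if (b < 0 || d < 0) stop("rates must be non-negative")
  if (root_count < 0) stop("root_count must be non-negative")
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    depth <- node_depths(tree)
    ebp <- edges_by_parent(tree)
    mult <- rep(1, nrow(tree$edge))
    if (!is.null(rate_multipliers)) {
      idx <- match(as.character(tree$edge[, 2]), names(rate_multipliers))
      if (anyNA(idx)) stop("rate_multipliers must be named by child node id")
      mult <- as.numeric(rate_multipliers[idx])
    }
    counts <- integer(n_tip + tree$Nnode)
    counts[root] <- as.integer(root_count)
    ev_edge <- integer(0); ev_type <- character(0)
    ev_time <- numeric(0); ev_lin <- integer(0); ev_root <- integer(0)
    tip_sp <- character(0); tip_lin <- integer(0); tip_root <- integer(0)
    lin_counter <- 0L
    cur_root <- 0L

    new_lineage <- function() { lin_counter <<- lin_counter + 1L; lin_counter }
    fmt <- function(x) sprintf("%.8f", max(x, 0))

    rec_node <- function(node, lin) {
      if (node <= n_tip) {
        tip_sp <<- c(tip_sp, tree$tip.label[node])
        tip_lin <<- c(tip_lin, lin)
        tip_root <<- c(tip_root, cur_root)
        return(list(nwk = paste0(tree$tip.label[node], "|L", lin),
                    time = depth[node]))
      }
      parts <- list()
      for (ke in ebp[[node]]) {
        p <- rec_branch(ke, lin)
        if (!is.null(p)) parts[[length(parts) + 1L]] <- p
      }
      if (length(parts) == 0) return(NULL)
      if (length(parts) == 1) return(parts[[1]])
      list(nwk = paste0("(", parts[[1]]$nwk, ":", fmt(parts[[1]]$time - depth[node]),
                        ",", parts[[2]]$nwk, ":", fmt(parts[[2]]$time - depth[node]), ")"),
           time = depth[node])
    }

    rec_branch <- function(ke, lin) {
      child <- tree$edge[ke, 2]
      m <- mult[ke]
      t_end <- depth[child]

      sim_lin <- function(lin, t_from) {
        rate <- (b + d) * m
        dt <- if (rate > 0) rexp(1, rate) else Inf
        if (t_from + dt >= t_end) {
          counts[child] <<- counts[child] + 1L
          return(rec_node(child, lin))
        }
        tev <- t_from + dt
        if (runif(1) < b / (b + d)) {
          ev_edge <<- c(ev_edge, child); ev_type <<- c(ev_type, "gain")
          ev_time <<- c(ev_time, tev); ev_lin <<- c(ev_lin, lin)
          ev_root <<- c(ev_root, cur_root)
          lin2 <- new_lineage()
          a1 <- sim_lin(lin, tev)
          a2 <- sim_lin(lin2, tev)
          if (is.null(a1)) return(a2)
          if (is.null(a2)) return(a1)
          list(nwk = paste0("(", a1$nwk, ":", fmt(a1$time - tev),
                            ",", a2$nwk, ":", fmt(a2$time - tev), ")"),
               time = tev)
        } else {
          ev_edge <<- c(ev_edge, child); ev_type <<- c(ev_type, "loss")
          ev_time <<- c(ev_time, tev); ev_lin <<- c(ev_lin, lin)
          ev_root <<- c(ev_root, cur_root)
          NULL
        }
      }
      sim_lin(lin, t_end - tree$edge.length[ke])
    }

    gene_trees <- vector("list", root_count)
    for (r in seq_len(root_count)) {
      cur_root <- r
      res <- rec_node(root, new_lineage())
      if (is.null(res)) {
        gene_trees[r] <- list(NULL)
      } else if (!grepl("(", res$nwk, fixed = TRUE)) {
        gene_trees[[r]] <- res$nwk  # singleton survivor: bare tip label
      } else {
        gene_trees[[r]] <- ape::read.tree(text = paste0(res$nwk, ";"))
      }
    }
    structure(list(
      family = family, b = b, d = d, root_count = as.integer(root_count),
      multipliers = setNames(mult, as.character(tree$edge[, 2])),
      counts = counts,
      events = data.frame(edge_child = ev_edge, type = ev_type, time = ev_time,
                          lineage = ev_lin, root_lineage = ev_root,
                          stringsAsFactors = FALSE),
      gene_trees = gene_trees,
      tips = data.frame(species = tip_sp, lineage = tip_lin,
                        root_lineage = tip_root, stringsAsFactors = FALSE),
      tree = tree), class = "family_history")
  })
}

#' Check birth-death bookkeeping on a simulated family history
#'
#' Asserts `count(child) = count(parent) + gains - losses` on every branch.
#'
#' @param history a `family_history`.
#' @return TRUE invisibly; errors on violation.
#' @export
check_bookkeeping <- function(history) {
  tree <- history$tree
  ev <- history$events
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    g <- sum(ev$type == "gain" & ev$edge_child == ch)
    l <- sum(ev$type == "loss" & ev$edge_child == ch)
    if (history$counts[ch] != history$counts[p] + g - l)
      stop("bookkeeping violated on branch to node ", ch)
  }
  if (any(history$counts < 0)) stop("negative copy number")
  invisible(TRUE)
}

#' Simulate four co-evolving receptor families with shared rate heterogeneity
#'
#' One log-normal rate multiplier is drawn per species-tree branch (mean 1 on
#' the natural scale) and shared by the OR, TAAR, and OlfC families; the ORA
#' family sees a dampened multiplier `m^ora_damp`. This emulates episodes of
#' expansion or contraction that affect the three dynamic families the same
#' way while leaving ORA comparatively stable.
#'
#' @param tree rooted species tree (`phylo`).
#' @param base_rates data.frame with columns `family`, `b`, `d`, `root_count`;
#'   defaults to empirically motivated per-family rates.
#' @param shared_multiplier_sd log-scale sd of the shared multiplier (>= 0;
#'   0 disables heterogeneity).
#' @param ora_damp dampening exponent for ORA (0 = constant multiplier 1).
#' @param seed RNG seed.
#' @return named list of four `family_history` objects, with the shared
#'   multipliers as attribute `multipliers`.
#' @export
simulate_coevolving_families <- function(tree, base_rates = default_family_rates(),
                                         shared_multiplier_sd = 0.8,
                                         ora_damp = 0.25, seed = NULL) {
  if (shared_multiplier_sd < 0) stop("shared_multiplier_sd must be >= 0")
  with_seed(seed, {
    E <- nrow(tree$edge)
    sdl <- shared_multiplier_sd
    m <- if (sdl > 0) rlnorm(E, meanlog = -sdl^2 / 2, sdlog = sdl) else rep(1, E)
    names(m) <- as.character(tree$edge[, 2])
    m_ora <- setNames(exp(ora_damp * log(m)), names(m))
    out <- list()
    for (i in seq_len(nrow(base_rates))) {
      fam <- base_rates$family[i]
      out[[fam]] <- simulate_family_counts(
        tree, b = base_rates$b[i], d = base_rates$d[i],
        root_count = base_rates$root_count[i],
        rate_multipliers = if (fam == "ORA") m_ora else m,
        seed = NULL, family = fam)
    }
    attr(out, "multipliers") <- m
    out
  })
}

#' Classify an olfactory epithelium by lamella count
#'
#' `flat` if the organ has at most two lamellae, `multilamellar` otherwise.
#'
#' @param lamellae integer vector of lamella counts.
#' @return character vector.
#' @export
epithelium_class <- function(lamellae) {
  ifelse(lamellae <= 2, "flat", "multilamellar")
}

#' Simulate lamella counts linearly linked to repertoire size
#'
#' `lamellae = max(0, round(intercept + slope * genes + e))` where `e` is a
#' Brownian-motion deviate on the tree (variance `bm_sigma^2` per My).
#'
#' @param tree rooted species tree (`phylo`).
#' @param total_gene_counts named numeric vector (species -> gene count);
#'   names must match the tree's tips.
#' @param intercept,slope linear link parameters.
#' @param bm_sigma Brownian sd per sqrt(My) (0 = deterministic link).
#' @param seed RNG seed.
#' @return data.frame: `species`, `total`, `lamellae`, `epithelium`.
#' @export
simulate_lamellae <- function(tree, total_gene_counts, intercept = 2,
                              slope = 0.08, bm_sigma = 0.5, seed = NULL) {
  if (!all(tree$tip.label %in% names(total_gene_counts)))
    stop("total_gene_counts must cover every species in the tree")
  if (!is.finite(slope) || !is.finite(bm_sigma)) stop("non-finite parameters")
  with_seed(seed, {
    counts <- total_gene_counts[tree$tip.label]
    n <- length(counts)
    dev <- rep(0, n)
    if (bm_sigma > 0) {
      V <- ape::vcv(tree)
      dev <- as.numeric(t(chol(V)) %*% rnorm(n)) * bm_sigma
    }
    lam <- pmax(0, round(intercept + slope * as.numeric(counts) + dev))
    data.frame(species = tree$tip.label, total = as.numeric(counts),
               lamellae = as.integer(lam),
               epithelium = epithelium_class(lam), stringsAsFactors = FALSE)
  })
}
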