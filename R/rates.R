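# Birth and death rates per gene per million years from branch event tables.
#
# Per retained branch: b = G / (N_parent * t), d = L / (N_parent * t).
# The pooled family estimator divides total events by total gene-time
# (sum of N_parent * t over retained branches), which is robust to short
# branches; the per-branch simple mean is reported alongside. Branches
# shorter than `min_branch_my` (default 2 My), the root stem (t undefined),
# and branches with no entering lineages are excluded with a reason.

#' Per-branch birth and death rates
#'
#' @param table a `branch_event_table` from [tabulate_branch_events()].
#' @param min_branch_my branches with `t` below this are excluded (default 2).
#' @return the table with columns `b`, `d`, `gene_time`, `excluded`,
#'   `exclude_reason` added.
#' @export
branch_rates <- function(table, min_branch_my = 2) {
  if (any(!is.na(table$t) & table$t < 0)) stop("negative branch length")
  excluded <- rep(FALSE, nrow(table))
  reason <- rep(NA_character_, nrow(table))
  stem <- is.na(table$t)
  short <- !stem & table$t < min_branch_my
  empty <- !stem & !short & table$N_parent == 0
  excluded[stem] <- TRUE; reason[stem] <- "stem"
  excluded[short] <- TRUE; reason[short] <- sprintf("t < %g My", min_branch_my)
  excluded[empty] <- TRUE; reason[empty] <- "N_parent = 0"
  gt <- ifelse(excluded, NA_real_, table$N_parent * table$t)
  out <- table
  out$b <- ifelse(excluded, NA_real_, table$G / gt)
  out$d <- ifelse(excluded, NA_real_, table$L / gt)
  out$gene_time <- gt
  out$excluded <- excluded
  out$exclude_reason <- reason
  out
}

#' Pooled family mean birth and death rates
#'
#' Pooled estimator: total gains (losses) divided by total gene-time over
#' retained branches; the per-branch arithmetic mean is reported as a
#' secondary estimate.
#'
#' @param rate_table output of [branch_rates()].
#' @return data.frame with one row per family: `b_pooled`, `d_pooled`,
#'   `b_branch_mean`, `d_branch_mean`, `gene_time`, `n_retained`. If every
#'   branch of a family is excluded the estimates are `NA` (undefined) with a
#'   warning.
#' @export
family_mean_rates <- function(rate_table) {
  fams <- unique(rate_table$family)
  rows <- lapply(fams, function(f) {
    tb <- rate_table[rate_table$family == f & !rate_table$excluded, , drop = FALSE]
    if (nrow(tb) == 0) {
      warning("all branches excluded for family ", f, "; rates undefined")
      return(data.frame(family = f, b_pooled = NA_real_, d_pooled = NA_real_,
                        b_branch_mean = NA_real_, d_branch_mean = NA_real_,
                        gene_time = 0, n_retained = 0L, stringsAsFactors = FALSE))
    }
    gt <- sum(tb$gene_time)
    data.frame(family = f,
               b_pooled = sum(tb$G) / gt, d_pooled = sum(tb$L) / gt,
               b_branch_mean = mean(tb$b), d_branch_mean = mean(tb$d),
               gene_time = gt, n_retained = nrow(tb), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Join a family's surviving root-lineage genealogies into one gene tree
#'
#' Receptor families are analysed as a single gene tree per family (the
#' family's common ancestor predates the species-tree root), so the recorded
#' per-root-lineage genealogies are attached to a basal spine. The spine
#' nodes map to the species root under LCA reconciliation; crucially, a root
#' lineage surviving only in part of the species tree then yields explicit
#' losses on the uncovered branches instead of an unobservable origination.
#'
#' @param history a `family_history`.
#' @return a rooted binary `phylo` (or a single tip label if only one copy
#'   survived anywhere; `NULL` if the family went extinct).
#' @export
family_gene_tree <- function(history) {
  parts <- character(0)
  for (gt in history$gene_trees) {
    if (is.null(gt)) next
    parts <- c(parts, if (is.character(gt)) gt
               else sub(";$", "", ape::write.tree(gt)))
  }
  if (length(parts) == 0) return(NULL)
  if (length(parts) == 1 && !grepl("(", parts[1], fixed = TRUE))
    return(parts[1])
  spine <- parts[1]
  for (p in parts[-1]) spine <- paste0("(", spine, ":1,", p, ":1):1")
  ape::read.tree(text = paste0(spine, ";"))
}

#' Branch event table from a simulated family history via reconciliation
#'
#' Convenience driver for validation: reconciles the history's gene trees
#' against the species tree and tabulates per-branch events. By default the
#' surviving root lineages are joined into one gene tree per family (see
#' [family_gene_tree()]), mirroring the one-alignment-per-family practice;
#' `join = FALSE` reconciles each root-lineage tree separately.
#'
#' @param history a `family_history`.
#' @param species_tree the species tree (defaults to the history's).
#' @param join reconcile one joined family tree (default) or per-lineage
#'   trees.
#' @param reroot use [root_and_reconcile()] instead of trusting the recorded
#'   rooting (slower; only sensible for small trees).
#' @return a `branch_event_table`.
#' @export
history_branch_events <- function(history, species_tree = history$tree,
                                  join = TRUE, reroot = FALSE) {
  recs <- list(); singles <- character(0)
  if (join) {
    gt <- family_gene_tree(history)
    if (is.null(gt)) {
      # extinct family: empty table
    } else if (is.character(gt)) {
      singles <- sub("\\|.*$", "", gt)
    } else if (reroot && length(gt$tip.label) >= 3) {
      recs <- list(root_and_reconcile(gt, species_tree))
    } else {
      recs <- list(lca_reconcile(gt, species_tree))
    }
  } else {
    for (gt in history$gene_trees) {
      if (is.null(gt)) next
      if (is.character(gt)) {
        singles <- c(singles, sub("\\|.*$", "", gt))
      } else if (length(gt$tip.label) == 2 || !reroot) {
        recs[[length(recs) + 1L]] <- lca_reconcile(gt, species_tree)
      } else {
        recs[[length(recs) + 1L]] <- root_and_reconcile(gt, species_tree)
      }
    }
  }
  tabulate_branch_events(recs, species_tree, family = history$family,
                         singletons = singles)
}
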