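# Duplication-loss reconciliation: support collapsing, LCA mapping, rooting,
# polytomy resolution, branch-event tabulation.

test_that("collapse_low_support contracts strictly-below-threshold nodes", {
  gt <- ape::read.tree(text = "(((a:1,b:1)89:1,c:2)95:1,d:3);")
  col <- collapse_low_support(gt, 90)
  expect_equal(col$Nnode, 2)  # the 89 node is gone, the 95 node stays
  expect_true(ape::is.rooted(col))

  gt90 <- ape::read.tree(text = "(((a:1,b:1)90:1,c:2)95:1,d:3);")
  expect_equal(collapse_low_support(gt90, 90)$Nnode, 3)  # boundary: retained

  full <- ape::read.tree(text = "(((a:1,b:1)100:1,c:2)100:1,d:3);")
  expect_true(ape::all.equal.phylo(collapse_low_support(full, 90), full,
                                   use.edge.length = FALSE))

  # nodes without a (numeric) support value are treated as resolved
  nolab <- ape::read.tree(text = "(((a:1,b:1):1,c:2)foo:1,d:3);")
  expect_equal(collapse_low_support(nolab, 90)$Nnode, 3)
})

test_that("lca_reconcile reproduces the textbook cases with placements", {
  stAB <- ape::read.tree(text = "(A:1,B:1);")
  g <- ape::read.tree(text = "((A|1:1,B|1:1):1,(A|2:1,B|2:1):1);")
  r <- lca_reconcile(g, stAB)
  expect_equal(r$duplications, 1)
  expect_equal(r$losses, 0)
  expect_equal(r$root_mapping, 3)  # species root
  expect_equal(unname(r$gains_by_branch["3"]), 1)  # root stem

  st <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  r2 <- lca_reconcile(ape::read.tree(text = "(A|1:1,C|1:1);"), st)
  expect_equal(r2$duplications, 0)
  expect_equal(r2$losses, 1)
  b_id <- match("B", st$tip.label)
  expect_equal(unname(r2$losses_by_branch[as.character(b_id)]), 1)

  # congruent gene tree: zero cost
  g3 <- ape::read.tree(text = "((A|1:1,B|1:1):1,C|1:2);")
  r3 <- lca_reconcile(g3, st)
  expect_equal(r3$cost, 0)

  expect_error(lca_reconcile(ape::read.tree(text = "(A|1:1,Z|1:1);"), st),
               "absent")
})

test_that("root_and_reconcile recovers the planted root and handles stars", {
  stAB <- ape::read.tree(text = "(A:1,B:1);")
  g <- ape::unroot(ape::read.tree(text = "((A|1,B|1),(A|2,B|2));"))
  r <- root_and_reconcile(g, stAB)
  expect_equal(r$cost, 1)
  expect_equal(r$duplications, 1)
  # recovered root separates {A|1,B|1} from {A|2,B|2} (or the symmetric pair)
  kids <- r$gene_tree$edge[r$gene_tree$edge[, 1] == 5, 2]
  clades <- lapply(kids, function(k) sort(ape::extract.clade(r$gene_tree, k)$tip.label))
  expect_true(list(c("A|1", "B|1")) %in% clades || list(c("A|2", "B|2")) %in% clades)

  st <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  star <- ape::read.tree(text = "(A|1,B|1,C|1);")
  expect_equal(root_and_reconcile(star, st)$cost, 0)

  # ties resolve deterministically
  r1 <- root_and_reconcile(g, stAB)
  r2 <- root_and_reconcile(g, stAB)
  expect_identical(ape::write.tree(r1$gene_tree), ape::write.tree(r2$gene_tree))
})

test_that("root_and_reconcile is optimal on random instances (scaled down)", {
  set.seed(17)
  for (r in 1:30) {
    ns <- sample(3:5, 1)
    st <- simulate_species_tree(ns, 10)
    st$tip.label <- sprintf("S%d", seq_len(ns))
    ng <- sample(3:6, 1)
    gt <- ape::rtree(ng, rooted = FALSE)
    gt$tip.label <- random_gene_tree_labels(ns, ng)
    if (ng >= 4 && runif(1) < 0.5)
      gt <- ape::di2multi(gt, tol = quantile(gt$edge.length, 0.35))
    expect_equal(root_and_reconcile(gt, st)$cost, min_dl_cost_oracle(gt, st))
  }
})

test_that("tabulate_branch_events places gains/losses and keeps bookkeeping", {
  stAB <- ape::read.tree(text = "(A:1,B:1);")
  g <- ape::read.tree(text = "((A|1:1,B|1:1):1,(A|2:1,B|2:1):1);")
  tab <- tabulate_branch_events(list(lca_reconcile(g, stAB)), stAB)
  stem <- tab[is.na(tab$parent), ]
  expect_equal(stem$G, 1)           # the duplication, on the root stem
  expect_equal(stem$origins, 1)
  expect_true(all(tab$G[!is.na(tab$parent)] == 0))
  expect_equal(tab$N_child[match(1:2, tab$branch_child)], c(2, 2))

  st <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  r2 <- lca_reconcile(ape::read.tree(text = "(A|1:1,C|1:1);"), st)
  tab2 <- tabulate_branch_events(list(r2), st)
  b_id <- match("B", st$tip.label)
  expect_equal(tab2$L[tab2$branch_child == b_id], 1)
  expect_equal(sum(tab2$L), 1)

  # zero-event reconciliations: all-zero table with correct N everywhere
  g3 <- ape::read.tree(text = "((A|1:1,B|1:1):1,C|1:2);")
  tab3 <- tabulate_branch_events(list(lca_reconcile(g3, st)), st)
  expect_true(all(tab3$G == 0) && all(tab3$L == 0))
  expect_true(all(tab3$N_child[match(1:3, tab3$branch_child)] == 1))

  # bookkeeping identity on every branch
  for (tb in list(tab, tab2, tab3)) {
    real <- !is.na(tb$parent)
    expect_true(all(tb$N_child[real] ==
                    tb$N_parent[real] + tb$G[real] + tb$origins[real] - tb$L[real]))
  }

  # singletons contribute originations at their species tip
  tab4 <- tabulate_branch_events(list(), st, singletons = c("C", "C"))
  expect_equal(tab4$origins[tab4$branch_child == match("C", st$tip.label)], 2)
  expect_equal(tab4$N_child[tab4$branch_child == match("C", st$tip.label)], 2)
})

test_that("reconciling true simulated gene trees recovers branch events", {
  # whenever the simulation produced no hidden events (no extinct subtrees),
  # LCA reconciliation of the true rooted gene trees must reproduce the
  # simulated per-branch gains exactly
  tr <- simulate_species_tree(6, 80, seed = 51)
  for (s in 1:20) {
    h <- simulate_family_counts(tr, 0.008, 0, 4, seed = 500 + s)  # d = 0: nothing hidden
    ev <- h$events
    # per-lineage reconciliation reproduces per-branch gains exactly
    tab <- history_branch_events(h, tr, join = FALSE)
    for (ch in tr$edge[, 2]) {
      want_g <- sum(ev$type == "gain" & ev$edge_child == ch)
      expect_equal(tab$G[tab$branch_child == ch], want_g)
    }
    expect_equal(sum(tab$G), sum(ev$type == "gain"))
    expect_equal(sum(tab$origins), length(h$gene_trees))
    # joined family tree: same gains on real branches; the basal spine adds
    # root-stem duplications and a single origination
    tabj <- history_branch_events(h, tr, join = TRUE)
    real <- !is.na(tabj$parent)
    expect_equal(tabj$G[real], tab$G[real])
    expect_equal(sum(tabj$origins), 1)
    expect_equal(sum(tabj$G) - sum(tab$G), length(h$gene_trees) - 1)
  }
})
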