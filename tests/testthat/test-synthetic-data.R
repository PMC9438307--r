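# Ground-truth simulators: species trees, birth-death family histories,
# genome emission, lamellae traits.

test_that("simulate_species_tree yields rooted binary ultrametric trees", {
  tr <- simulate_species_tree(2, 80, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(unname(olfrep:::node_depths(tr)[1:2]), c(80, 80), tolerance = 1e-9)

  expect_identical(ape::write.tree(simulate_species_tree(9, 120, seed = 5)),
                   ape::write.tree(simulate_species_tree(9, 120, seed = 5)))
  expect_error(simulate_species_tree(1, 10, seed = 1), ">= 2")

  # property: many random trees all pass the ultrametricity and shape checks
  for (s in 1:60) {
    tr <- simulate_species_tree(10, 50, seed = s)
    expect_silent(validate_time_tree(tr))
  }
})

test_that("simulate_family_counts: degenerate settings and bookkeeping", {
  tr <- simulate_species_tree(6, 100, seed = 2)
  h0 <- simulate_family_counts(tr, 0, 0, 7, seed = 3)
  expect_true(all(h0$counts == 7))
  expect_equal(nrow(h0$events), 0)

  hz <- simulate_family_counts(tr, 0.01, 0.01, 0, seed = 3)
  expect_true(all(hz$counts == 0))
  expect_equal(nrow(hz$events), 0)

  expect_error(simulate_family_counts(tr, -0.1, 0, 5), "non-negative")
  expect_error(simulate_family_counts(tr, 0.1, 0, -2), "non-negative")

  # bookkeeping property over random simulations
  for (s in 1:25) {
    h <- simulate_family_counts(tr, 0.01, 0.006, 5, seed = 100 + s)
    expect_true(check_bookkeeping(h))
    # gene-tree tip totals agree with recorded tip counts
    n_tips <- sum(vapply(h$gene_trees, function(g) {
      if (is.null(g)) 0L else if (is.character(g)) 1L else length(g$tip.label)
    }, 1L))
    expect_equal(n_tips, sum(h$counts[seq_along(tr$tip.label)]))
    expect_equal(nrow(h$tips), n_tips)
  }
})

test_that("tip-count mean matches the linear birth-death expectation", {
  # E[N_T] = N0 * exp((b - d) * T); cherry tree of depth T, 3 settings,
  # Monte-Carlo tolerance of 3 standard errors
  tr <- ape::read.tree(text = "(A:100,B:100);")
  settings <- list(c(b = 0.010, d = 0.005, n0 = 20),
                   c(b = 0.004, d = 0.004, n0 = 10),
                   c(b = 0.000, d = 0.006, n0 = 30))
  set.seed(99)
  for (st in settings) {
    reps <- 600
    tips <- vapply(seq_len(reps), function(i) {
      h <- simulate_family_counts(tr, st[["b"]], st[["d"]], st[["n0"]])
      h$counts[1]
    }, 1)
    expected <- st[["n0"]] * exp((st[["b"]] - st[["d"]]) * 100)
    se <- sd(tips) / sqrt(reps)
    expect_lt(abs(mean(tips) - expected), 3 * se + 1e-9)
  }
})

test_that("shared multipliers couple OR/TAAR/OlfC and dampen ORA", {
  tr <- simulate_species_tree(20, 200, seed = 4)
  h0 <- simulate_coevolving_families(tr, shared_multiplier_sd = 0, seed = 5)
  expect_true(all(attr(h0, "multipliers") == 1))
  expect_true(all(h0$OR$multipliers == 1))

  h1 <- simulate_coevolving_families(tr, shared_multiplier_sd = 0.8,
                                     ora_damp = 0, seed = 6)
  expect_true(all(h1$ORA$multipliers == 1))
  expect_identical(h1$OR$multipliers, h1$TAAR$multipliers)

  # with sd > 0, per-branch gains of OR and TAAR correlate positively in
  # most replicates (scaled-down version of the power property)
  pos <- 0; reps <- 30
  for (s in seq_len(reps)) {
    hh <- simulate_coevolving_families(tr, shared_multiplier_sd = 0.8, seed = 200 + s)
    gb <- function(h) {
      ev <- h$events[h$events$type == "gain", ]
      tab <- table(factor(ev$edge_child, levels = tr$edge[, 2]))
      as.numeric(tab)
    }
    r <- branch_correlation(gb(hh$OR), gb(hh$TAAR))$r
    if (r > 0) pos <- pos + 1
  }
  expect_gte(pos / reps, 0.95)
})

test_that("emit_genomes respects state fractions and truth consistency", {
  tree <- simulate_species_tree(2, 30, seed = 21)
  rates <- olfrep:::default_family_rates()
  rates$root_count <- c(4L, 3L, 2L, 2L)
  hists <- simulate_coevolving_families(tree, rates, shared_multiplier_sd = 0,
                                        seed = 22)
  panel <- reference_panel()

  all_gene <- emit_genomes(tree, hists, panel, pseudo_fraction = 0,
                           truncated_fraction = 0, edge_fraction = 0, seed = 23)
  expect_true(all(all_gene$truth$status == "gene"))
  expect_true(all(all_gene$truth$lof == ""))

  all_pseudo <- emit_genomes(tree, hists, panel, pseudo_fraction = 1,
                             truncated_fraction = 0, edge_fraction = 0, seed = 23)
  expect_true(all(all_pseudo$truth$status == "pseudogene"))
  expect_true(all(nchar(all_pseudo$truth$lof) > 0))

  expect_error(emit_genomes(tree, hists, panel, pseudo_fraction = 0.7,
                            truncated_fraction = 0.4, edge_fraction = 0), "sum")
  expect_error(emit_genomes(tree, hists, panel[0, ], seed = 1), "empty")

  # determinism: same seed -> byte-identical genomes
  a <- emit_genomes(tree, hists, panel, seed = 24)
  b <- emit_genomes(tree, hists, panel, seed = 24)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth, b$truth)

  # per-species per-family locus counts equal the history tip counts
  for (h in hists) {
    for (sp in tree$tip.label) {
      want <- h$counts[match(sp, tree$tip.label)]
      got <- sum(a$truth$species == sp & a$truth$family == h$family)
      expect_equal(got, want)
    }
  }

  # every locus appears exactly once
  expect_equal(anyDuplicated(a$truth$locus_id), 0)

  # edge loci lie < 30 bp from a contig border
  ed <- a$truth[a$truth$status == "edge", ]
  if (nrow(ed) > 0) {
    for (i in seq_len(nrow(ed))) {
      clen <- nchar(a$genomes[[ed$species[i]]][[ed$contig[i]]])
      expect_lt(min(ed$start[i], clen - ed$end[i]), 30)
    }
  }

  # "gene" loci re-translate to a stop-free ORF starting with Met
  genes <- all_gene$truth[all_gene$truth$family == "OR", ][1:5, ]  # intronless
  for (i in seq_len(nrow(genes))) {
    ctg <- all_gene$genomes[[genes$species[i]]][[genes$contig[i]]]
    body <- substr(ctg, genes$start[i] + 1, genes$end[i])
    if (genes$strand[i] == "-") body <- olfrep:::revcomp(body)
    aa <- olfrep:::translate_cds(body)
    expect_identical(substr(aa, 1, 1), "M")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("simulate_lamellae follows the linear link and the flat rule", {
  tr <- simulate_species_tree(6, 100, seed = 31)
  counts <- setNames(rep(100, 6), tr$tip.label)
  tt <- simulate_lamellae(tr, counts, intercept = 0, slope = 0.1, bm_sigma = 0)
  expect_true(all(tt$lamellae == 10))
  expect_true(all(tt$epithelium == "multilamellar"))

  expect_identical(epithelium_class(c(0, 2, 3, 40)),
                   c("flat", "flat", "multilamellar", "multilamellar"))

  expect_error(simulate_lamellae(tr, c(a = 1), seed = 1), "cover every species")
})
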