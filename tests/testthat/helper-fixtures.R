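# Shared fixture builders for the mining tests: a synthetic multi-species
# genome with known locus states, plus a scorer comparing mined loci to the
# truth table.

make_mining_fixture <- function(n_species = 3, crown = 50, root_counts = c(6, 4, 3, 3),
                                pseudo = 0.2, truncated = 0.1, edge = 0.1,
                                shared_sd = 0.5, seed = 11) {
  tree <- simulate_species_tree(n_species, crown, seed = seed)
  rates <- olfrep:::default_family_rates()
  rates$root_count <- as.integer(root_counts)
  hists <- simulate_coevolving_families(tree, rates, shared_multiplier_sd = shared_sd,
                                        seed = seed + 1L)
  panel <- reference_panel()
  em <- emit_genomes(tree, hists, panel, pseudo_fraction = pseudo,
                     truncated_fraction = truncated, edge_fraction = edge,
                     seed = seed + 2L)
  list(tree = tree, hists = hists, panel = panel,
       genomes = em$genomes, truth = em$truth)
}

# match mined loci to truth rows by interval overlap; returns per-locus stats
score_mining <- function(truth_sp, loci) {
  n <- nrow(truth_sp)
  found <- fam_ok <- st_ok <- logical(n)
  for (i in seq_len(n)) {
    cand <- loci[loci$contig == truth_sp$contig[i] &
                 loci$start < truth_sp$end[i] & loci$end > truth_sp$start[i], ]
    if (nrow(cand) >= 1) {
      found[i] <- TRUE
      fam_ok[i] <- cand$family[1] == truth_sp$family[i]
      st_ok[i] <- cand$status[1] == truth_sp$status[i]
    }
  }
  list(recall = mean(found),
       family_acc = if (any(found)) mean(fam_ok[found]) else NA_real_,
       status_acc = if (any(found)) mean(st_ok[found]) else NA_real_,
       n = n, found = found, fam_ok = fam_ok, st_ok = st_ok)
}

# a gene_model-like list for classification tests (classification depends
# only on these fields)
fake_model <- function(coverage = 1, n_lof = 0, has_start = TRUE,
                       has_terminal_stop = TRUE) {
  lof <- if (n_lof > 0)
    data.frame(kind = rep("premature_stop", n_lof), cds_pos = seq_len(n_lof) * 50L)
  else data.frame(kind = character(0), cds_pos = integer(0))
  structure(list(coverage = coverage, lof = lof, has_start = has_start,
                 has_terminal_stop = has_terminal_stop), class = "gene_model")
}
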