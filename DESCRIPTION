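Package: olfrep
Title: Evolutionary Dynamics of Olfactory Receptor Gene Repertoires in Fishes
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to study the evolution of the four main olfactory receptor
    gene families (OR, TAAR, OlfC, ORA) in ray-finned fishes. Provides a
    desk-scale gene-mining pipeline (six-frame translated Smith-Waterman
    search, hit-region merging, protein-to-genome spliced alignment with
    frameshift and intron states, family assignment against a decoy-aware
    reference panel, and gene/pseudogene/truncated/edge classification),
    duplication-loss gene-tree/species-tree reconciliation with per-branch
    gain and loss tabulation, birth and death rate estimation per gene per
    million years with short-branch exclusion, and phylogenetic comparative
    statistics (PGLS with maximum-likelihood Pagel's lambda, phylogenetic
    signal tests, per-branch event correlations). A synthetic-data module
    simulates species trees, birth-death gene-family histories with shared
    branch-rate heterogeneity, sequence-level genomes with known locus
    states, and correlated lamellae traits, providing ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
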