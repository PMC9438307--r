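# Synthetic reference receptor panel.
#
# Real pipelines query genomes with curated OR/TAAR/OlfC/ORA proteins and
# re-classify candidates against a decoy-aware GPCR database. At desk scale
# the panel is generated: one base coding sequence per family (mutually
# unrelated random sequences, so cross-family similarity is background-level),
# subfamily exemplars diverged ~8% from their family base (seven OR
# subfamilies alpha..eta; ORA1..ORA8), and unrelated decoy "GPCR" proteins.

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

OR_SUBFAMILIES <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta")
ORA_SUBFAMILIES <- paste0("ORA", 1:8)
FAMILIES <- c("OR", "TAAR", "OlfC", "ORA")

# run expr with a private RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, n_codons - 1L, replace = TRUE), collapse = ""),
         "TGA")  # terminal stop included
}

# substitute `n_sub` random interior sites; never touches the start codon or
# terminal stop and redraws any substitution that would create an in-frame stop
mutate_cds <- function(cds, n_sub) {
  if (n_sub <= 0) return(cds)
  bases <- strsplit(cds, "", fixed = TRUE)[[1]]
  L <- length(bases)
  interior <- 4:(L - 3)
  pos <- sample(interior, min(n_sub, length(interior)))
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), bases[p])
    for (b in sample(alt)) {
      old <- bases[p]
      bases[p] <- b
      cstart <- p - ((p - 1) %% 3)
      if (!is_stop_codon(paste(bases[cstart:(cstart + 2)], collapse = ""))) break
      bases[p] <- old
    }
  }
  paste(bases, collapse = "")
}

#' Generate the synthetic reference receptor panel
#'
#' Returns a data frame of labelled reference sequences: per-family base
#' sequences (used as translated-search queries), subfamily exemplars (the
#' BLASTX-style classification database), and unrelated decoy GPCR proteins.
#' All sequences are synthetic; family identity is encoded by sequence
#' similarity, not by biology.
#'
#' @param seed RNG seed (the panel is deterministic given the seed).
#' @param exemplar_divergence per-site divergence of subfamily exemplars from
#'   their family base (default 0.08).
#' @return data.frame with columns `id`, `family`, `subfamily`, `role`
#'   (`seed`, `panel` or `decoy`), `cds` (with terminal stop), `protein`.
#' @export
reference_panel <- function(seed = 42L, exemplar_divergence = 0.08) {
  with_seed(seed, {
    lens <- c(OR = 312L, TAAR = 345L, OlfC = 380L, ORA = 310L)  # codons incl. stop
    rows <- list()
    for (fam in FAMILIES) {
      base <- random_cds(lens[[fam]])
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(fam, "_base"), family = fam, subfamily = NA_character_,
        role = "seed", cds = base, stringsAsFactors = FALSE)
      subs <- switch(fam, OR = OR_SUBFAMILIES, ORA = ORA_SUBFAMILIES,
                     paste0(fam, "-", c("I", "II")))
      for (sf in subs) {
        n_sub <- round(exemplar_divergence * nchar(base))
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(fam, "_", sf), family = fam, subfamily = sf,
          role = "panel", cds = mutate_cds(base, n_sub), stringsAsFactors = FALSE)
      }
    }
    for (k in 1:3) {
      cds <- random_cds(330L)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("decoyGPCR_", k), family = "non-olfactory",
        subfamily = NA_character_, role = "decoy", cds = cds,
        stringsAsFactors = FALSE)
    }
    panel <- do.call(rbind, rows)
    panel$protein <- vapply(panel$cds, function(x)
      sub("\\*$", "", translate_cds(x)), "", USE.NAMES = FALSE)
    panel
  })
}

panel_seeds <- function(panel) panel[panel$role == "seed", , drop = FALSE]
panel_db <- function(panel) panel[panel$role != "seed", , drop = FALSE]
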