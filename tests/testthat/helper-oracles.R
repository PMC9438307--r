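# Independent oracles used by the test suite. These deliberately avoid the
# package's own alignment/reconciliation code paths: plain-R dynamic
# programmes, exhaustive enumeration, and ape/phangorn built-ins.

# ---- scoring setup ----------------------------------------------------------

oracle_blosum <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

oracle_encode_aa <- function(p, sm) {
  match(strsplit(toupper(p), "", fixed = TRUE)[[1]], rownames(sm))
}

# ---- local affine Smith-Waterman, full quadratic DP -------------------------

sw_score_oracle <- function(a_idx, b_idx, sm, go = 11, ge = 1) {
  m <- length(a_idx); n <- length(b_idx)
  G <- go + ge
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - G, E[i, j - 1] - ge)
    F[i, j] <- max(H[i - 1, j] - G, F[i - 1, j] - ge)
    s <- if (is.na(a_idx[i - 1]) || is.na(b_idx[j - 1])) -4
         else sm[a_idx[i - 1], b_idx[j - 1]]
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# six-frame translated SW score via Biostrings' genetic code
translated_sw_oracle <- function(contig, query, sm, go = 11, ge = 1) {
  gc <- Biostrings::GENETIC_CODE
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  translate1 <- function(d) {
    n <- nchar(d) %/% 3
    if (n == 0) return("")
    cods <- substring(d, 3 * seq_len(n) - 2, 3 * seq_len(n))
    aa <- gc[cods]; aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  q <- oracle_encode_aa(query, sm)
  best <- 0
  for (s in c(contig, rc(contig))) {
    for (f in 0:2) {
      t <- translate1(substring(s, f + 1))
      if (nchar(t) == 0) next
      best <- max(best, sw_score_oracle(q, oracle_encode_aa(t, sm), sm, go, ge))
    }
  }
  best
}

# ---- spliced alignment score by branch-and-bound enumeration ----------------

# Same model as the package aligner: units of 3 bases (codon, BLOSUM score or
# stop penalty), 1/2/4/5 bases (frameshift penalty), residue skip, in-frame
# codon insertion, and GT..AG introns of >= min_intron bases between codon
# units (codon must follow the intron). Alignments are local and must start
# with a codon unit. Exhaustive over all unit sequences with an admissible
# upper bound (max BLOSUM score per remaining residue) for pruning.
spliced_score_oracle <- function(prot, dna, cfg, sm) {
  p <- oracle_encode_aa(prot, sm)
  gc <- Biostrings::GENETIC_CODE
  m <- length(p); n <- nchar(dna)
  ch <- strsplit(toupper(dna), "", fixed = TRUE)[[1]]
  codon_at <- function(j) paste(ch[(j - 2):j], collapse = "")  # ends at j
  aa_of <- function(cd) { a <- gc[cd]; if (is.na(a)) "X" else a }
  csc <- function(i, j) {
    cd <- codon_at(j); a <- aa_of(cd)
    if (a == "*") return(cfg$stop_penalty)
    ai <- p[i]; bi <- match(a, rownames(sm))
    if (is.na(ai) || is.na(bi)) -4 else sm[ai, bi]
  }
  maxres <- max(sm)
  best <- 0
  intron_exits <- function(j) {
    # intron starting at j+1 (GT) of length >= min_intron ending with AG at j2
    if (j + cfg$min_intron > n) return(integer(0))
    if (!(ch[j + 1] == "G" && ch[j + 2] == "T")) return(integer(0))
    j2 <- (j + cfg$min_intron):n
    j2[ch[j2 - 1] == "A" & ch[j2] == "G"]
  }
  rec <- function(i, j, sc) {
    if (sc > best) best <<- sc
    if (i >= m) return()
    if (sc + (m - i) * maxres <= best) return()   # admissible bound
    # codon
    if (j + 3 <= n) rec(i + 1, j + 3, sc + csc(i + 1, j + 3))
    # frameshift units
    for (w in c(1, 2, 4, 5)) if (j + w <= n)
      rec(i + 1, j + w, sc + cfg$fs_penalty)
    # residue skip
    rec(i + 1, j, sc + cfg$gap_res_penalty)
    # codon insertion
    if (j + 3 <= n) {
      pen <- cfg$gap_dna_penalty
      if (aa_of(codon_at(j + 3)) == "*") pen <- pen + cfg$stop_penalty
      rec(i, j + 3, sc + pen)
    }
    # intron then codon
    for (j2 in intron_exits(j)) if (j2 + 3 <= n)
      rec(i + 1, j2 + 3, sc + cfg$intron_penalty + csc(i + 1, j2 + 3))
  }
  for (i0 in 0:(m - 1)) for (j0 in 0:(n - 3)) {
    rec(i0 + 1, j0 + 3, csc(i0 + 1, j0 + 3))
  }
  best
}

# ---- duplication-loss cost via ape built-ins --------------------------------

dl_cost_oracle <- function(gt, st) {
  stopifnot(ape::is.binary(gt), ape::is.rooted(gt))
  n_tip <- length(gt$tip.label)
  sp <- sub("\\|.*$", "", gt$tip.label)
  st1 <- st; st1$edge.length <- rep(1, nrow(st$edge))
  de <- ape::node.depth.edgelength(st1)   # edge-count depth per species node
  gmrca <- function(tips) {
    ids <- match(unique(sp[tips]), st$tip.label)
    if (length(ids) == 1) ids else ape::getMRCA(st, ids)
  }
  desc <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(gt$edge[gt$edge[, 1] == node, 2], desc))
  }
  n_node <- n_tip + gt$Nnode
  M <- integer(n_node)
  for (v in seq_len(n_node)) M[v] <- gmrca(desc(v))
  dup <- rep(FALSE, n_node)
  for (v in (n_tip + 1):n_node) {
    kids <- gt$edge[gt$edge[, 1] == v, 2]
    dup[v] <- any(M[kids] == M[v])
  }
  losses <- 0
  for (k in seq_len(nrow(gt$edge))) {
    u <- gt$edge[k, 1]; v <- gt$edge[k, 2]
    losses <- losses + (de[M[v]] - de[M[u]]) - (!dup[u])
  }
  sum(dup) + losses
}

# canonical unrooted splits of a tree, as sorted tip-name strings
splits_oracle <- function(tr) {
  if (ape::is.rooted(tr)) tr <- tryCatch(ape::unroot(tr), error = function(e) tr)
  n_tip <- length(tr$tip.label)
  desc <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(tr$edge[tr$edge[, 1] == node, 2], desc))
  }
  sp <- character(0)
  for (k in seq_len(nrow(tr$edge))) {
    v <- tr$edge[k, 2]
    if (v <= n_tip) next
    tips <- sort(tr$tip.label[desc(v)])
    if (length(tips) < 2 || length(tips) > n_tip - 2) next
    comp <- sort(setdiff(tr$tip.label, tips))
    side <- if (paste(tips, collapse = ",") < paste(comp, collapse = ","))
      tips else comp
    sp <- c(sp, paste(side, collapse = ","))
  }
  sort(unique(sp))
}

# minimum DL cost over every rooted binary tree whose unrooted topology
# refines the given (possibly multifurcating, arbitrarily rooted) gene tree
min_dl_cost_oracle <- function(gt, st) {
  labs <- gt$tip.label
  cands <- phangorn::allTrees(length(labs), rooted = TRUE, tip.label = labs)
  need <- splits_oracle(gt)
  best <- Inf
  for (i in seq_along(cands)) {
    b <- cands[[i]]   # [[ ]] re-attaches tip labels on compressed multiPhylo
    have <- splits_oracle(b)
    if (!all(need %in% have)) next
    b$edge.length <- rep(1, nrow(b$edge))
    best <- min(best, dl_cost_oracle(b, st))
  }
  best
}

# ---- GLS matrix oracle ------------------------------------------------------

gls_oracle <- function(X, y, V) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Vi %*% r)
  list(beta = as.numeric(beta), rss = rss)
}

# ---- misc -------------------------------------------------------------------

random_gene_tree_labels <- function(n_species, n_genes) {
  spp <- sprintf("S%d", seq_len(n_species))
  paste0(sample(spp, n_genes, replace = TRUE), "|g", seq_len(n_genes))
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")

random_protein_str <- function(n) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV",
                                                        "")[[1]], n, TRUE),
                                        collapse = "")
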