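# Sequence-level genome emission with known locus states.
#
# Tip copies from simulated family histories are turned into genomic loci:
# coding sequences evolve along the recorded genealogy (Jukes-Cantor,
# codon-position-uniform, never creating stops outside injected lesions),
# OR loci are intronless while TAAR/OlfC/ORA loci carry 1-2 GT..AG introns,
# and a configurable fraction of loci is emitted as pseudogenes (injected
# premature stops / 1-bp frameshifts), truncated models, or contig-edge
# fragments. The emitted FASTA plus truth table is the ground truth the
# mining stage is scored against.

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# JC69 expected per-site substitution probability over time t
jc_p <- function(rate, t) 0.75 * (1 - exp(-4 / 3 * rate * t))

# evolve a CDS along a branch of length t; at least one substitution per
# branch so that paralogs stay distinguishable
evolve_cds <- function(cds, rate, t) {
  interior <- nchar(cds) - 6L
  n <- max(1L, rbinom(1, interior, jc_p(rate, max(t, 0))))
  mutate_cds(cds, n)
}

# evolve sequences along one gene tree; returns named character vector of
# tip CDS (names = tip labels)
evolve_along_gene_tree <- function(gtree, root_cds, rate, stem_length) {
  root_seq <- evolve_cds(root_cds, rate, stem_length)
  if (is.character(gtree)) return(setNames(root_seq, gtree))  # singleton
  n_tip <- length(gtree$tip.label)
  seqs <- character(n_tip + gtree$Nnode)
  seqs[n_tip + 1L] <- root_seq
  for (k in reorder_edges_preorder(gtree)) {
    p <- gtree$edge[k, 1]; ch <- gtree$edge[k, 2]
    seqs[ch] <- evolve_cds(seqs[p], rate, gtree$edge.length[k])
  }
  setNames(seqs[seq_len(n_tip)], gtree$tip.label)
}

# pick `n` LOF lesions on a CDS: returns data.frame(kind, pos) with positions
# in original CDS coordinates, interior only (>30 bp from both ends), clear of
# the supplied intron boundaries
draw_lof <- function(cds_len, n, intron_pts) {
  lo <- 31L; hi <- cds_len - 31L
  pos <- integer(0); kind <- character(0)
  guard <- 0L
  while (length(pos) < n && guard < 200L) {
    guard <- guard + 1L
    p <- sample(lo:hi, 1)
    if (length(intron_pts) && any(abs(p - intron_pts) <= 4)) next
    if (length(pos) && any(abs(p - pos) <= 4)) next
    pos <- c(pos, p)
    kind <- c(kind, sample(c("premature_stop", "frameshift"), 1))
  }
  data.frame(kind = kind, pos = pos, stringsAsFactors = FALSE)
}

# apply LOF lesions to a CDS; returns list(seq, shift_at) where shift_at maps
# original coordinates to cumulative indel shift
apply_lof <- function(cds, lof) {
  bases <- strsplit(cds, "", fixed = TRUE)[[1]]
  shifts <- data.frame(pos = numeric(0), delta = numeric(0))
  if (nrow(lof)) for (i in order(lof$pos, decreasing = TRUE)) {
    p <- lof$pos[i]
    if (lof$kind[i] == "premature_stop") {
      cstart <- p - ((p - 1) %% 3)
      bases[cstart:(cstart + 2)] <- strsplit(sample(c("TAA", "TGA", "TAG"), 1), "")[[1]]
    } else if (runif(1) < 0.5) {
      bases <- append(bases, sample(c("A", "C", "G", "T"), 1), after = p)
      shifts <- rbind(shifts, data.frame(pos = p, delta = 1))
    } else {
      bases <- bases[-p]
      shifts <- rbind(shifts, data.frame(pos = p, delta = -1))
    }
  }
  shift_at <- function(q) {
    if (nrow(shifts) == 0) return(q)
    q + sum(shifts$delta[shifts$pos < q])
  }
  list(seq = paste(bases, collapse = ""), shift_at = shift_at)
}

# assemble a gene body: CDS (possibly LOF-edited) with introns inserted at
# original-frame codon boundaries
build_gene_body <- function(cds, lof, n_introns) {
  L0 <- nchar(cds)
  intron_pts <- integer(0)
  if (n_introns > 0) {
    cands <- seq(60L, L0 - 60L, by = 3L)
    intron_pts <- sort(sample(cands, n_introns))
    while (length(intron_pts) > 1 && diff(intron_pts) < 60) {
      intron_pts <- sort(sample(cands, n_introns))
    }
  }
  ed <- apply_lof(cds, lof)
  seq <- ed$seq
  # insert introns right-to-left at shifted coordinates; record their
  # positions in the final body so truncation points can avoid them
  intron_iv <- matrix(integer(0), 0, 2)
  for (p in rev(intron_pts)) {
    ps <- ed$shift_at(p)
    ilen <- sample(80:240, 1)
    intr <- paste0("GT", random_dna(ilen - 4L), "AG")
    seq <- paste0(substr(seq, 1, ps), intr, substr(seq, ps + 1, nchar(seq)))
    intron_iv <- rbind(c(ps + 1L, ps + ilen), intron_iv)
    if (nrow(intron_iv) > 1)
      intron_iv[-1, ] <- intron_iv[-1, , drop = FALSE] + ilen
  }
  attr(seq, "introns") <- intron_iv
  seq
}

# draw a cut length (from `side` of a `len`-bp body) whose boundary lands in
# exonic sequence, so that a border truncation is attributable to the border
draw_exonic_cut <- function(len, introns, side) {
  for (try in 1:40) {
    cut <- round(runif(1, 0.25, 0.45) * len)
    boundary <- if (side == "start") cut + 1L else len - cut
    inside <- nrow(introns) > 0 &&
      any(boundary >= introns[, 1] & boundary <= introns[, 2])
    if (!inside) return(cut)
  }
  cut
}

#' Emit synthetic genomes and a ground-truth locus table
#'
#' Turns family histories into per-species genome FASTA with loci in the four
#' functional states (`gene`, `pseudogene`, `truncated`, `edge`). Every tip
#' copy in every history is emitted exactly once; loci on a shared contig are
#' separated by at least `2 * flank` of random intergenic sequence, and edge
#' loci sit within 30 bp of a contig border.
#'
#' @param tree the species tree the histories were simulated on.
#' @param histories list of `family_history` objects (one per family).
#' @param panel reference panel from [reference_panel()]; root lineages take
#'   their ancestral sequence from the family's subfamily exemplars.
#' @param subst_rate substitutions per site per My along the gene genealogy.
#' @param pseudo_fraction,truncated_fraction,edge_fraction expected fractions
#'   of loci emitted in each non-intact state (must sum to <= 1).
#' @param flank flank length used downstream by region extension (bp).
#' @param seed RNG seed.
#' @return list with `genomes` (named list: species -> named character vector
#'   of contigs) and `truth` (data.frame: one row per emitted locus).
#' @export
emit_genomes <- function(tree, histories, panel, subst_rate = 5e-4,
                         pseudo_fraction = 0.1, truncated_fraction = 0.05,
                         edge_fraction = 0.05, flank = 5000L, seed = NULL) {
  fr <- c(pseudo_fraction, truncated_fraction, edge_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("state fractions must lie in [0,1] and sum to <= 1")
  if (is.null(panel) || nrow(panel) == 0) stop("empty reference panel")
  with_seed(seed, {
    depth_max <- max(node_depths(tree))
    loci <- list()  # per species: list of locus specs
    for (sp in tree$tip.label) loci[[sp]] <- list()
    for (h in histories) {
      fam <- h$family
      ex <- panel[panel$family == fam & panel$role == "panel", , drop = FALSE]
      if (nrow(ex) == 0) stop("no panel exemplars for family ", fam)
      n_introns_for <- function() if (fam == "OR") 0L else sample(1:2, 1)
      for (r in seq_along(h$gene_trees)) {
        gt <- h$gene_trees[[r]]
        if (is.null(gt)) next
        exi <- ((r - 1L) %% nrow(ex)) + 1L
        stem <- if (is.character(gt)) depth_max
                else max(depth_max - max(node_depths(gt)), 0)
        tipseqs <- evolve_along_gene_tree(gt, ex$cds[exi], subst_rate, stem)
        for (lab in names(tipseqs)) {
          sp <- sub("\\|.*$", "", lab)
          loci[[sp]][[length(loci[[sp]]) + 1L]] <- list(
            family = fam, subfamily = ex$subfamily[exi], label = lab,
            cds = tipseqs[[lab]], n_introns = n_introns_for())
        }
      }
    }
    statuses <- c("pseudogene", "truncated", "edge", "gene")
    pr <- c(fr, 1 - sum(fr))
    genomes <- list(); truth <- list()
    for (sp in tree$tip.label) {
      ll <- loci[[sp]]
      if (length(ll) == 0) { genomes[[sp]] <- setNames(character(0), character(0)); next }
      ll <- ll[sample(length(ll))]
      for (i in seq_along(ll)) {
        st <- sample(statuses, 1, prob = pr)
        lof <- if (st == "pseudogene")
          draw_lof(nchar(ll[[i]]$cds), sample(1:3, 1), integer(0)) else
          data.frame(kind = character(0), pos = integer(0))
        ll[[i]]$status <- st
        ll[[i]]$lof <- lof
        ll[[i]]$body <- build_gene_body(ll[[i]]$cds, lof, ll[[i]]$n_introns)
        ll[[i]]$strand <- sample(c("+", "-"), 1)
      }
      is_edge <- vapply(ll, function(x) x$status == "edge", TRUE)
      ctg_seqs <- character(0); rows <- list(); ctg_i <- 0L
      emit_contig <- function(pieces) {
        # pieces: list of list(seq) / list(locus=...) already ordered
        ctg_i <<- ctg_i + 1L
        name <- sprintf("%s_ctg%02d", sp, ctg_i)
        pos <- 0L; seqs <- character(0)
        for (p in pieces) {
          if (!is.null(p$locus)) {
            lr <- p$locus
            rows[[length(rows) + 1L]] <<- data.frame(
              species = sp, contig = name, start = pos,
              end = pos + nchar(p$seq), strand = lr$strand,
              family = lr$family, subfamily = lr$subfamily,
              status = lr$status,
              locus_id = paste0(lr$family, ":", lr$label),
              lof = if (nrow(lr$lof)) paste(paste0(lr$lof$kind, "@", lr$lof$pos),
                                            collapse = ";") else "",
              stringsAsFactors = FALSE)
          }
          seqs <- c(seqs, p$seq); pos <- pos + nchar(p$seq)
        }
        ctg_seqs[name] <<- paste(seqs, collapse = "")
      }
      place <- function(l) if (l$strand == "+") l$body else unname(revcomp(l$body))
      # edge loci: one per contig, truncated at the border (the cut lands in
      # exonic sequence so incompleteness is attributable to the border)
      for (l in ll[is_edge]) {
        placed <- place(l)
        plen <- nchar(placed)
        iv <- attr(l$body, "introns")
        if (is.null(iv)) iv <- matrix(integer(0), 0, 2)
        if (l$strand == "-" && nrow(iv) > 0)
          iv <- cbind(plen - iv[, 2] + 1L, plen - iv[, 1] + 1L)
        dborder <- sample(0:25, 1)
        side <- sample(c("start", "end"), 1)
        cut <- draw_exonic_cut(plen, iv, side)
        if (side == "start") {
          rem <- substr(placed, cut + 1L, nchar(placed))
          emit_contig(list(list(seq = random_dna(dborder)),
                           list(seq = rem, locus = l),
                           list(seq = random_dna(sample(800:1500, 1)))))
        } else {
          rem <- substr(placed, 1L, nchar(placed) - cut)
          emit_contig(list(list(seq = random_dna(sample(800:1500, 1))),
                           list(seq = rem, locus = l),
                           list(seq = random_dna(dborder))))
        }
      }
      # remaining loci: contigs of 1-3, generous internal spacing
      rest <- ll[!is_edge]
      while (length(rest) > 0) {
        k <- min(length(rest), sample(1:3, 1))
        pieces <- list(list(seq = random_dna(sample(600:1500, 1))))
        for (j in seq_len(k)) {
          l <- rest[[j]]
          body <- place(l)
          if (l$status == "truncated") {
            cut <- round(runif(1, 0.25, 0.45) * nchar(body))
            body <- if (sample(c(TRUE, FALSE), 1)) substr(body, cut + 1L, nchar(body))
                    else substr(body, 1L, nchar(body) - cut)
          }
          pieces[[length(pieces) + 1L]] <- list(seq = body, locus = l)
          pieces[[length(pieces) + 1L]] <- list(
            seq = random_dna(if (j < k) 2L * flank + sample(500:1500, 1)
                             else sample(600:1500, 1)))
        }
        emit_contig(pieces)
        rest <- rest[-seq_len(k)]
      }
      genomes[[sp]] <- ctg_seqs
      truth[[sp]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    truth_df <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
    rownames(truth_df) <- NULL
    list(genomes = genomes, truth = truth_df)
  })
}
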