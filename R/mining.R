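# Receptor-locus mining: a desk-scale re-implementation of the classic
# TBLASTN -> extend -> spliced-align -> BLASTX-reclassify -> curate chain.
#
# The translated search runs a six-frame local Smith-Waterman (BLOSUM62,
# affine gaps) over sliding windows; E-values use the Karlin-Altschul form
# E = K * m * n * exp(-lambda * S) with gapped BLOSUM62 constants, m = query
# length (aa) and n = contig length (nt). Hit regions are extended by `flank`
# bp on both sides, merged, and each merged region is aligned to its
# best-matching reference protein with the spliced aligner (frameshift,
# stop-readthrough and GT..AG intron states). Candidates are then assigned a
# family against the decoy-aware panel and classified as
# gene / pseudogene / truncated / edge.

karlin_evalue <- function(score, m, n, cfg) {
  cfg$karlin_k * m * n * exp(-cfg$karlin_lambda * score)
}

karlin_bits <- function(score, cfg) {
  (cfg$karlin_lambda * score - log(cfg$karlin_k)) / log(2)
}

translate_frames <- function(seq) {
  # three forward-frame translations, returned as BLOSUM62-row-encoded
  # integer vectors (stops encoded as the '*' row, unknowns as -1)
  enc <- encode_dna(seq)
  L <- length(enc)
  tab <- codon_aa_table()
  out <- vector("list", 3)
  for (f in 0:2) {
    n <- (L - f) %/% 3
    if (n < 1) { out[[f + 1]] <- integer(0); next }
    i1 <- seq.int(f + 1, by = 3, length.out = n)
    b1 <- enc[i1]; b2 <- enc[i1 + 1]; b3 <- enc[i1 + 2]
    cods <- 16L * b1 + 4L * b2 + b3
    bad <- b1 < 0 | b2 < 0 | b3 < 0
    cods[bad] <- 0L
    aidx <- tab[cods + 1L]
    aidx[bad] <- -1L
    out[[f + 1]] <- aidx
  }
  out
}

#' Six-frame translated local search of a contig
#'
#' Scans a contig with protein queries in all six reading frames using a
#' local Smith-Waterman over sliding windows, reporting hits with
#' Karlin-Altschul E-value below the configured threshold.
#'
#' @param contig a DNA string.
#' @param query_proteins named character vector of protein queries.
#' @param config a [run_config()].
#' @param contig_name label used in the output.
#' @return data.frame of hits sorted by contig position: `contig`, `start`,
#'   `end` (0-based half-open, forward strand), `strand`, `frame`, `score`,
#'   `bits`, `evalue`, `query`.
#' @export
translated_search <- function(contig, query_proteins, config = run_config(),
                              contig_name = "contig") {
  if (length(query_proteins) == 0) stop("empty query set")
  if (nchar(contig) < 1) stop("empty contig")
  L <- nchar(contig)
  sm <- the$blosum62
  qenc <- lapply(query_proteins, encode_protein)
  win <- config$search_window; step <- config$search_step
  starts <- if (L <= win) 1L else unique(c(seq(1L, L - win + 1L, by = step), L - win + 1L))
  hits <- list()
  for (ws in starts) {
    wseq <- substr(contig, ws, min(ws + win - 1L, L))
    wlen <- nchar(wseq)
    frames <- list(`+` = translate_frames(wseq), `-` = translate_frames(revcomp(wseq)))
    for (strand in c("+", "-")) {
      for (f in 0:2) {
        tenc <- frames[[strand]][[f + 1]]
        if (length(tenc) == 0) next
        for (qi in seq_along(qenc)) {
          r <- .sw_local_cpp(qenc[[qi]], tenc, sm, config$gap_open, config$gap_extend)
          if (r$score <= 0) next
          ev <- karlin_evalue(r$score, length(qenc[[qi]]), L, config)
          if (ev >= config$e_value_threshold) next
          s_nt <- f + 3L * (r$b_start - 1L)        # 0-based within oriented window
          e_nt <- f + 3L * r$b_end
          if (strand == "-") { tmp <- s_nt; s_nt <- wlen - e_nt; e_nt <- wlen - tmp }
          hits[[length(hits) + 1L]] <- data.frame(
            contig = contig_name, start = ws - 1L + s_nt, end = ws - 1L + e_nt,
            strand = strand, frame = f, score = r$score,
            bits = karlin_bits(r$score, config), evalue = ev,
            query = names(query_proteins)[qi], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(contig = character(0), start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0), score = numeric(0),
                      bits = numeric(0), evalue = numeric(0), query = character(0),
                      stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  # windows overlap: collapse same-query overlapping hits, keeping the best
  h <- h[order(h$query, h$start, h$end), , drop = FALSE]
  cl <- integer(nrow(h)); cur <- 0L; last_end <- -1L; last_q <- ""
  for (i in seq_len(nrow(h))) {
    if (h$query[i] != last_q || h$start[i] >= last_end) {
      cur <- cur + 1L; last_end <- h$end[i]
    } else last_end <- max(last_end, h$end[i])
    last_q <- h$query[i]; cl[i] <- cur
  }
  keep <- vapply(split(seq_len(nrow(h)), cl),
                 function(ix) ix[which.max(h$score[ix])], 1L)
  h <- h[sort(keep), , drop = FALSE]
  h <- h[order(h$start, h$end), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Merge and extend translated-search hits into candidate regions
#'
#' Each hit interval is extended by `flank` bp on both sides, clamped to the
#' contig, and overlapping extended intervals are unioned. Each region keeps
#' the query of its best-scoring hit.
#'
#' @param hits hit data.frame from [translated_search()] (one contig).
#' @param contig_length contig length in bp.
#' @param flank extension in bp (default 5000).
#' @return data.frame `start`, `end` (0-based half-open), `query`, `score`;
#'   regions are pairwise disjoint and sorted.
#' @export
merge_hit_regions <- function(hits, contig_length, flank = 5000L) {
  if (nrow(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      query = character(0), score = numeric(0)))
  s <- pmax(0L, hits$start - as.integer(flank))
  e <- pmin(as.integer(contig_length), hits$end + as.integer(flank))
  strand <- if ("strand" %in% names(hits)) hits$strand else rep("+", nrow(hits))
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]; q <- hits$query[ord]; sc <- hits$score[ord]
  st <- strand[ord]
  rs <- s[1]; re <- e[1]; rq <- q[1]; rsc <- sc[1]; rst <- st[1]
  out <- list()
  flush <- function() data.frame(start = rs, end = re, query = rq, score = rsc,
                                 strand = rst, stringsAsFactors = FALSE)
  for (i in seq_along(s)[-1]) {
    if (s[i] < re) {
      re <- max(re, e[i])
      if (sc[i] > rsc) { rsc <- sc[i]; rq <- q[i]; rst <- st[i] }
    } else {
      out[[length(out) + 1L]] <- flush()
      rs <- s[i]; re <- e[i]; rq <- q[i]; rsc <- sc[i]; rst <- st[i]
    }
  }
  out[[length(out) + 1L]] <- flush()
  do.call(rbind, out)
}

#' Spliced protein-to-genome alignment of one candidate region
#'
#' Aligns a reference protein to a genomic region under a dynamic programme
#' with codon match, frameshift (1/2/4/5-base), stop-readthrough, and GT..AG
#' intron states; both strands are tried. Frameshifts and in-frame stops
#' traversed by the best alignment are recorded as loss-of-function events.
#'
#' @param reference_protein reference protein string (no terminal stop).
#' @param region_sequence genomic region (DNA string).
#' @param config a [run_config()].
#' @param strand `"both"` (default), `"+"` or `"-"`: restrict the search to
#'   one strand (e.g. when the seeding hit already fixed it).
#' @return a `gene_model` list (`NULL` if no alignment scores above 0):
#'   `score`, `strand`, `exons` (0-based half-open forward-region coords),
#'   `cds`, `protein`, `coverage`, `lof` (data.frame `kind`, `cds_pos`),
#'   `has_start`, `has_terminal_stop`, `q_start`, `q_end`, `d_start`, `d_end`.
#' @export
spliced_align <- function(reference_protein, region_sequence, config = run_config(),
                          strand = "both") {
  penc <- encode_protein(reference_protein)
  m <- length(penc)
  sm <- the$blosum62
  run1 <- function(dseq) {
    .spliced_align_cpp(penc, encode_dna(dseq), sm, codon_aa_table(),
                       stop_aa_index(), config$fs_penalty, config$gap_res_penalty,
                       config$gap_dna_penalty, config$intron_penalty,
                       config$stop_penalty, config$min_intron)
  }
  rl <- nchar(region_sequence)
  fwd <- if (strand %in% c("both", "+")) run1(region_sequence) else list(score = -1L)
  rev <- if (strand %in% c("both", "-")) run1(unname(revcomp(region_sequence)))
         else list(score = -1L)
  use_rev <- rev$score > fwd$score
  r <- if (use_rev) rev else fwd
  if (r$score <= 0) return(NULL)
  oriented <- if (use_rev) unname(revcomp(region_sequence)) else region_sequence
  # terminal stop: local alignment may shed a few diverged terminal residues,
  # so look for an in-frame stop where the reference's remaining residues end
  # -- but only within a small shed window, so a genuinely truncated model
  # cannot pick up a chance stop far away
  shed_max <- 5L
  has_stop <- FALSE
  if (m - r$q_end <= shed_max) {
    for (off in 0:max(0, m - r$q_end)) {
      nxt <- substr(oriented, r$d_end + 3L * off + 1L, r$d_end + 3L * off + 3L)
      if (nchar(nxt) == 3 && is_stop_codon(nxt)) { has_stop <- TRUE; break }
    }
  }
  # initial Met: aligned directly, or in-frame at the exact offset where the
  # reference's few shed leading residues would begin
  start_at <- r$d_start - 3L * (r$q_start - 1L)
  has_start <- if (r$q_start == 1L) substr(r$cds, 1, 3) == "ATG" else
    r$q_start - 1L <= shed_max && start_at >= 1L &&
      substr(oriented, start_at, start_at + 2L) == "ATG"
  exons <- r$exons  # 1-based inclusive on oriented seq
  if (use_rev) {
    ex <- cbind(rl - exons[, 2], rl - exons[, 1] + 1L)   # 0-based half-open fwd
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    d0 <- rl - r$d_end; d1 <- rl - r$d_start + 1L
  } else {
    ex <- cbind(exons[, 1] - 1L, exons[, 2])
    d0 <- r$d_start - 1L; d1 <- r$d_end
  }
  structure(list(
    score = r$score, strand = if (use_rev) "-" else "+",
    exons = ex, cds = r$cds, protein = r$protein,
    coverage = (r$q_end - r$q_start + 1) / m,
    lof = data.frame(kind = as.character(r$event_kind),
                     cds_pos = as.integer(r$event_pos), stringsAsFactors = FALSE),
    has_start = has_start,
    has_terminal_stop = has_stop,
    q_start = r$q_start, q_end = r$q_end,
    d_start = d0, d_end = d1, reference = NULL), class = "gene_model")
}

#' Classify a locus as gene, pseudogene, truncated, or edge
#'
#' Rules, in order of precedence: at least one loss-of-function event makes a
#' `pseudogene` (regardless of completeness); a complete model (reference
#' coverage at least `completeness_fraction`, initial Met, terminal stop)
#' without LOF is a `gene`; an incomplete LOF-free model is `edge` when its
#' distance to a contig border is below `edge_distance` bp, else `truncated`.
#'
#' @param model a `gene_model`.
#' @param distance_to_contig_border bp between the locus and the nearest
#'   contig end.
#' @param edge_distance border threshold in bp (default 30).
#' @param completeness_fraction minimum reference coverage (default 0.8).
#' @return one of `"gene"`, `"pseudogene"`, `"truncated"`, `"edge"`.
#' @export
classify_locus <- function(model, distance_to_contig_border, edge_distance = 30L,
                           completeness_fraction = 0.8) {
  if (nrow(model$lof) >= 1) return("pseudogene")
  complete <- model$coverage >= completeness_fraction &&
    isTRUE(model$has_start) && isTRUE(model$has_terminal_stop)
  if (complete) return("gene")
  if (distance_to_contig_border < edge_distance) return("edge")
  "truncated"
}

sw_protein_score <- function(a_enc, b_enc, cfg) {
  .sw_local_cpp(a_enc, b_enc, the$blosum62, cfg$gap_open, cfg$gap_extend)$score
}

#' Assign a candidate protein to a receptor family
#'
#' BLASTX-style: the candidate is scored against every member of the labelled
#' panel (including decoy GPCRs); the best-scoring member's family and
#' subfamily are returned. A best-scoring decoy means `non-olfactory`
#' (discard). When the top two scores are within `margin_bits`, the call is
#' flagged ambiguous.
#'
#' @param candidate_protein protein string.
#' @param panel reference panel ([reference_panel()]); `seed`-role rows are
#'   not part of the classification database.
#' @param config a [run_config()].
#' @return list: `family`, `subfamily`, `ambiguous`, `best_id`, `bits`.
#' @export
assign_family <- function(candidate_protein, panel, config = run_config()) {
  if (is.null(candidate_protein) || nchar(candidate_protein) == 0)
    stop("empty candidate protein")
  db <- panel_db(panel)
  cenc <- encode_protein(candidate_protein)
  scores <- vapply(db$protein, function(p)
    sw_protein_score(cenc, encode_protein(p), config), 0, USE.NAMES = FALSE)
  bits <- karlin_bits(scores, config)
  ord <- order(bits, decreasing = TRUE)
  best <- ord[1]
  ambiguous <- length(ord) > 1 && (bits[ord[1]] - bits[ord[2]]) < config$margin_bits
  list(family = db$family[best], subfamily = db$subfamily[best],
       ambiguous = ambiguous, best_id = db$id[best], bits = bits[best])
}

# neighbour-joining placement check: a reproducible stand-in for tree-based
# visual curation. The candidate joins the panel in an NJ tree built from
# normalised SW distances; it is retained iff its nearest panel leaf is
# olfactory (non-decoy).
nj_curation <- function(candidate_protein, panel, config = run_config(),
                        panel_scores = NULL) {
  db <- panel_db(panel)
  cenc <- encode_protein(candidate_protein)
  encs <- lapply(db$protein, encode_protein)
  if (is.null(panel_scores)) panel_scores <- panel_score_matrix(panel, config)
  n <- nrow(db)
  S <- matrix(0, n + 1, n + 1)
  S[seq_len(n), seq_len(n)] <- panel_scores
  for (i in seq_len(n)) S[i, n + 1] <- S[n + 1, i] <- sw_protein_score(cenc, encs[[i]], config)
  S[n + 1, n + 1] <- sw_protein_score(cenc, cenc, config)
  D <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n + 1)) for (j in seq_len(n + 1))
    D[i, j] <- 1 - S[i, j] / min(S[i, i], S[j, j])
  labs <- c(db$id, ".candidate")
  rownames(D) <- colnames(D) <- labs
  tr <- ape::nj(as.dist(D))
  co <- ape::cophenetic.phylo(tr)[".candidate", db$id]
  nn <- db[which.min(co), ]
  nn$family != "non-olfactory"
}

panel_score_matrix <- function(panel, config = run_config()) {
  db <- panel_db(panel)
  encs <- lapply(db$protein, encode_protein)
  n <- length(encs)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    S[i, j] <- S[j, i] <- sw_protein_score(encs[[i]], encs[[j]], config)
  }
  S
}

#' Collapse identical coding sequences within one genome
#'
#' Exact nucleotide duplicates are collapsed to the first locus in
#' (contig, start) order.
#'
#' @param loci locus data.frame with `cds`, `contig`, `start` columns.
#' @return list: `loci` (reduced, original order), `removed` (count).
#' @export
dedup_identical <- function(loci) {
  if (nrow(loci) == 0) return(list(loci = loci, removed = 0L))
  ord <- order(loci$contig, loci$start)
  l2 <- loci[ord, , drop = FALSE]
  dup <- duplicated(l2$cds)
  list(loci = l2[!dup, , drop = FALSE], removed = sum(dup))
}

#' Mine one genome for receptor loci
#'
#' Runs the whole chain: six-frame translated search with the panel's
#' family-seed queries, hit-region extension and merging, spliced alignment
#' (first against the seeding query, then re-aligned against the best panel
#' member), BLASTX-style family assignment with decoys, NJ-placement
#' curation, status classification, and exact-duplicate removal.
#'
#' @param genome named character vector of contig sequences.
#' @param panel reference panel ([reference_panel()]).
#' @param config a [run_config()].
#' @return list: `loci` (one row per retained locus), `repertoire`
#'   (family x status count matrix), `removed_duplicates`, `config`.
#' @export
mine_genome <- function(genome, panel, config = run_config()) {
  seeds <- panel_seeds(panel)
  queries <- setNames(seeds$protein, seeds$id)
  pscores <- panel_score_matrix(panel, config)
  rows <- list()
  for (cn in names(genome)) {
    contig <- genome[[cn]]
    clen <- nchar(contig)
    hits <- translated_search(contig, queries, config, contig_name = cn)
    if (nrow(hits) == 0) next
    regions <- merge_hit_regions(hits, clen, config$flank)
    for (ri in seq_len(nrow(regions))) {
      rs <- regions$start[ri]; re <- regions$end[ri]
      rseq <- substr(contig, rs + 1L, re)
      seed_prot <- queries[[regions$query[ri]]]
      model <- spliced_align(seed_prot, rseq, config, strand = regions$strand[ri])
      if (is.null(model)) next
      fam <- assign_family(model$protein, panel, config)
      if (fam$family == "non-olfactory") next
      best <- panel[panel$id == fam$best_id, ]
      if (best$protein != seed_prot) {
        # re-align against the best panel member on a narrowed window around
        # the first model (the locus position is already pinned down)
        ns <- max(0L, model$d_start - 500L); ne <- min(re - rs, model$d_end + 500L)
        model2 <- spliced_align(best$protein, substr(rseq, ns + 1L, ne), config,
                                strand = model$strand)
        if (!is.null(model2)) {
          model2$d_start <- model2$d_start + ns; model2$d_end <- model2$d_end + ns
          model2$exons <- model2$exons + ns
          model <- model2
          fam <- assign_family(model$protein, panel, config)
          if (fam$family == "non-olfactory") next
        }
      }
      if (!nj_curation(model$protein, panel, config, pscores)) next
      lstart <- rs + model$d_start; lend <- rs + model$d_end
      dist_border <- min(lstart, clen - lend)
      status <- classify_locus(model, dist_border, config$edge_distance,
                               config$completeness_fraction)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cn, start = lstart, end = lend, strand = model$strand,
        family = fam$family, subfamily = fam$subfamily, status = status,
        coverage = model$coverage, n_lof = nrow(model$lof),
        has_start = model$has_start, has_terminal_stop = model$has_terminal_stop,
        score = model$score, ambiguous = fam$ambiguous, cds = model$cds,
        stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), family = character(0),
               subfamily = character(0), status = character(0),
               coverage = numeric(0), n_lof = integer(0),
               has_start = logical(0), has_terminal_stop = logical(0),
               score = numeric(0), ambiguous = logical(0), cds = character(0),
               stringsAsFactors = FALSE)
  dd <- dedup_identical(loci)
  loci <- dd$loci
  rownames(loci) <- NULL
  statuses <- c("gene", "pseudogene", "truncated", "edge")
  rep_tab <- matrix(0L, length(FAMILIES), length(statuses),
                    dimnames = list(FAMILIES, statuses))
  if (nrow(loci)) {
    tt <- table(factor(loci$family, levels = FAMILIES),
                factor(loci$status, levels = statuses))
    rep_tab[] <- as.integer(tt)
  }
  list(loci = loci, repertoire = rep_tab, removed_duplicates = dd$removed,
       config = config)
}
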