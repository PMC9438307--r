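# Receptor-locus mining: translated search, region merging, spliced
# alignment, status classification, family assignment, dedup, driver.

cfg <- run_config()

test_that("translated_search finds exact inserts on both strands", {
  panel <- reference_panel()
  cds <- panel$cds[panel$id == "OR_base"]
  prot <- setNames(panel$protein[panel$id == "OR_base"], "q")
  set.seed(1)
  contig <- paste0(random_dna_str(800), cds, random_dna_str(800))
  h <- translated_search(contig, prot, cfg, "c")
  expect_equal(nrow(h), 1)
  expect_identical(h$strand, "+")
  expect_lt(h$evalue, 1e-10)
  expect_equal(h$start, 800)
  expect_equal(h$end, 800 + nchar(cds) - 3)  # terminal stop not matched

  rc <- olfrep:::revcomp(contig)
  h2 <- translated_search(rc, prot, cfg, "c")
  expect_identical(h2$strand, "-")
  expect_equal(h2$score, h$score)  # strand symmetry of the raw score
  expect_equal(h2$start, nchar(contig) - h$end)

  expect_error(translated_search(contig, character(0), cfg), "empty query")
})

test_that("translated_search matches the brute-force translated SW oracle", {
  sm <- oracle_blosum()
  set.seed(12)
  for (r in 1:12) {
    contig <- random_dna_str(sample(120:500, 1))
    q <- random_protein_str(sample(15:50, 1))
    # plant a partial match half the time so scores are not all background
    if (r %% 2 == 0) {
      frag <- paste(rep("ATG", 12), collapse = "")
      contig <- paste0(contig, frag, contig)
      q <- paste0(q, strrep("M", 12))
    }
    got <- translated_search(contig, c(q = q),
                             run_config(e_value_threshold = 1e300), "c")
    want <- translated_sw_oracle(contig, q, sm)
    if (want > 0) {
      expect_equal(max(got$score), want)
    } else {
      expect_true(nrow(got) == 0 || max(got$score) <= 0)
    }
  }
})

test_that("merge_hit_regions extends, merges, and clamps", {
  mk <- function(s, e) data.frame(contig = "c", start = s, end = e,
                                  strand = "+", frame = 0, score = 100,
                                  bits = 50, evalue = 0, query = "q")
  r <- merge_hit_regions(mk(6000, 6300), 20000, 5000)
  expect_equal(c(r$start, r$end), c(1000, 11300))

  r <- merge_hit_regions(mk(100, 400), 20000, 5000)
  expect_equal(c(r$start, r$end), c(0, 5400))

  r <- merge_hit_regions(rbind(mk(6000, 6300), mk(12000, 12300)), 20000, 5000)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(1000, 17300))

  r <- merge_hit_regions(rbind(mk(2000, 2300), mk(30000, 30300)), 40000, 5000)
  expect_equal(nrow(r), 2)
  expect_true(all(r$end[-nrow(r)] <= r$start[-1]))  # pairwise disjoint
})

test_that("spliced_align handles exact, intron, frameshift and stop cases", {
  panel <- reference_panel()
  ref <- panel$protein[panel$id == "TAAR_base"]
  cds <- panel$cds[panel$id == "TAAR_base"]
  set.seed(5)
  pad <- function(x) paste0(random_dna_str(300), x, random_dna_str(300))

  m <- spliced_align(ref, pad(cds), cfg)
  expect_equal(nrow(m$exons), 1)
  expect_equal(m$coverage, 1)
  expect_equal(nrow(m$lof), 0)
  expect_true(m$has_start && m$has_terminal_stop)

  body <- paste0(substr(cds, 1, 402), "GT", random_dna_str(196), "AG",
                 substr(cds, 403, nchar(cds)))
  m2 <- spliced_align(ref, pad(body), cfg)
  expect_equal(nrow(m2$exons), 2)
  expect_identical(m2$protein, ref)  # translated protein identical to reference

  del <- paste0(substr(cds, 1, 149), substr(cds, 151, nchar(cds)))
  m3 <- spliced_align(ref, pad(del), cfg)
  expect_equal(m3$lof$kind, "frameshift")
  expect_lt(abs(m3$lof$cds_pos - 150), 6)

  stp <- paste0(substr(cds, 1, 300), "TGA", substr(cds, 304, nchar(cds)))
  m4 <- spliced_align(ref, pad(stp), cfg)
  expect_true("premature_stop" %in% m4$lof$kind)

  expect_null(spliced_align("MKL", "CCCCCCCCCCCC", cfg))
})

test_that("spliced_align equals exhaustive enumeration on toy regions", {
  sm <- oracle_blosum()
  toy_cfg <- run_config(min_intron = 6L)
  set.seed(31)
  for (r in 1:10) {
    prot <- random_protein_str(sample(5:8, 1))
    dna <- random_dna_str(sample(20:40, 1))
    # plant partial codon-structure half the time
    if (r %% 2 == 0) {
      ins <- paste(vapply(strsplit(substr(prot, 1, 4), "")[[1]], function(a)
        names(which(Biostrings::GENETIC_CODE == a))[1], ""), collapse = "")
      dna <- paste0(substr(dna, 1, 6), ins, substr(dna, 7, nchar(dna)))
    }
    want <- spliced_score_oracle(prot, dna, toy_cfg, sm)
    got <- spliced_align(prot, dna, toy_cfg, strand = "+")
    expect_equal(if (is.null(got)) 0 else got$score, want)
  }
})

test_that("classify_locus applies the four-state rules with precedence", {
  expect_identical(classify_locus(fake_model(), 1000), "gene")
  expect_identical(classify_locus(fake_model(n_lof = 1), 1000), "pseudogene")
  expect_identical(classify_locus(fake_model(coverage = 0.5), 500), "truncated")
  expect_identical(classify_locus(fake_model(coverage = 0.5), 10), "edge")
  # pseudogene precedence over incompleteness
  expect_identical(classify_locus(fake_model(coverage = 0.4, n_lof = 2), 10),
                   "pseudogene")
})

test_that("assign_family labels by best panel hit, decoys discard, ties flag", {
  panel <- reference_panel()
  cand <- panel$protein[panel$id == "OR_delta"]
  a <- assign_family(cand, panel, cfg)
  expect_identical(a$family, "OR")
  expect_identical(a$subfamily, "delta")
  expect_false(a$ambiguous)

  dec <- assign_family(panel$protein[panel$id == "decoyGPCR_1"], panel, cfg)
  expect_identical(dec$family, "non-olfactory")

  # equidistant candidate: duplicate a panel member under two labels
  p2 <- panel
  twin <- p2[p2$id == "OR_delta", ]
  twin$id <- "TAAR_twin"; twin$family <- "TAAR"; twin$subfamily <- NA
  p2 <- rbind(p2, twin)
  tie <- assign_family(cand, p2, cfg)
  expect_true(tie$ambiguous)

  expect_error(assign_family("", panel, cfg), "empty candidate")
})

test_that("dedup_identical collapses exact duplicates deterministically", {
  loci <- data.frame(contig = c("c2", "c1", "c3"), start = c(5L, 9L, 1L),
                     cds = c("AAA", "AAA", "CCC"), stringsAsFactors = FALSE)
  d <- dedup_identical(loci)
  expect_equal(d$removed, 1L)
  expect_identical(sort(d$loci$contig), c("c1", "c3"))

  all_diff <- data.frame(contig = "c", start = 1:3, cds = c("A", "C", "G"))
  expect_equal(dedup_identical(all_diff)$removed, 0L)

  tri <- data.frame(contig = "c", start = c(3L, 1L, 2L), cds = rep("AAA", 3))
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    d <- dedup_identical(tri[perm, ])
    expect_equal(nrow(d$loci), 1)
    expect_equal(d$loci$start, 1L)  # first in (contig, start) order survives
  }
})

test_that("mine_genome on an empty genome yields an empty table", {
  panel <- reference_panel()
  set.seed(77)
  res <- mine_genome(list(c1 = random_dna_str(4000)), panel, cfg)
  expect_equal(nrow(res$loci), 0)
  expect_true(all(res$repertoire == 0))
})

test_that("mining is deterministic and strand-symmetric", {
  fx <- make_mining_fixture(n_species = 2, root_counts = c(3, 2, 1, 1),
                            pseudo = 0.25, truncated = 0, edge = 0, seed = 41)
  sp <- fx$tree$tip.label[1]
  g <- as.list(fx$genomes[[sp]])
  r1 <- mine_genome(g, fx$panel, cfg)
  r2 <- mine_genome(g, fx$panel, cfg)
  expect_identical(r1$loci, r2$loci)

  grc <- lapply(g, function(x) unname(olfrep:::revcomp(x)))
  r3 <- mine_genome(grc, fx$panel, cfg)
  expect_identical(r1$repertoire, r3$repertoire)
  # coordinates mirror
  ord1 <- order(r1$loci$contig, r1$loci$start)
  m1 <- r1$loci[ord1, ]
  m3 <- r3$loci[order(r3$loci$contig, -r3$loci$start), ]
  for (i in seq_len(nrow(m1))) {
    clen <- nchar(g[[m1$contig[i]]])
    expect_equal(m3$start[i], clen - m1$end[i])
    expect_equal(m3$end[i], clen - m1$start[i])
    expect_identical(m3$status[i], m1$status[i])
  }

  # status partition: every locus has exactly one status; counts sum
  expect_equal(sum(r1$repertoire), nrow(r1$loci))
  expect_true(all(r1$loci$status %in% c("gene", "pseudogene", "truncated", "edge")))
})
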