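---
title: "Methods: models, algorithms and validation design in olfrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, algorithms and validation design in olfrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`olfrep` re-implements, at desk scale, the computational chain used to link
olfactory-receptor gene repertoires to olfactory-organ morphology in
ray-finned fishes: mining receptor loci from genome sequence and classifying
them as gene / pseudogene / truncated / edge; reconciling gene trees with a
time-calibrated species tree to obtain per-branch gene gains and losses;
converting those events into birth and death rates per gene per million
years; and phylogenetic comparative regression (PGLS with Pagel's λ).
Because the original study's inputs (185 public genome assemblies and a
published fish chronogram) are not reproducible in a small, offline
environment, the package ships a first-class synthetic-data module that
simulates the entire data-generating process with known ground truth, and
every downstream stage is validated against that truth or against
independent brute-force oracles.

# The mining model

## Translated search

Contigs are scanned with protein queries in all six reading frames using a
local Smith–Waterman with BLOSUM62 and affine gaps (open 11, extend 1, the
BLAST convention: a gap of length *k* costs 11 + *k*). Significance uses the
Karlin–Altschul form

E = K·m·n·exp(−λS),  λ = 0.267, K = 0.041 (gapped BLOSUM62 constants),

with *m* the query length (aa) and *n* the contig length (nt), thresholded
at E < 1e−10. This reproduces BLAST-like thresholding behaviour without
re-estimating the statistics; at these parameters any credible receptor
fragment (≳ 60 aligned residues) passes and random matches never do. Long
contigs are scanned in 12 kb windows with 6 kb steps — with loci separated
by ≥ 2 × 5000 bp of intergenic sequence, a window never straddles two whole
loci, and duplicate window hits merge downstream. Hit regions are extended
5000 bp on each side, clamped to the contig, and unioned.

## Spliced alignment

Each candidate region is aligned to its best-matching reference protein
under a dynamic programme whose states mirror a protein-to-genome aligner:

* **codon unit** — 3 bases against one reference residue (BLOSUM62 score);
  an in-frame stop codon scores −25 and is recorded as a `premature_stop`
  loss-of-function (LOF) event;
* **frameshift unit** — 1, 2, 4 or 5 bases for one residue, −20, recorded
  as a `frameshift` LOF event;
* **residue skip** (−12) and in-frame codon insertion (−12);
* **intron** — ≥ 30 bases starting `GT` and ending `AG`, −15, allowed only
  between codon units.

Alignment is local at both ends and must start and end on a codon unit. The
stop/frameshift penalties are deliberately smaller than the score of the
~10+ downstream residues that a true pseudogene still aligns, so lesions
are read through rather than truncating the model; they are large enough
that a diverged but intact gene never "invents" a lesion (mismatch costs
≈ −2, an order of magnitude cheaper). Both the search and the spliced
aligner are verified cell-for-cell against independent plain-R
implementations (full quadratic DP; branch-and-bound enumeration of all
unit decompositions on toy regions).

## Classification

A model is **complete** when it covers ≥ 80% of its best-matching reference
protein and has an initial Met and a terminal stop. Start/stop detection
tolerates up to 5 terminal residues shed by the local alignment, looking at
the exact in-frame offset where the reference's missing residues would sit;
the window is capped because an unbounded search will eventually find a
chance in-frame `ATG` in flanking sequence (1/64 per position) and promote
a truncated model to a gene. Status follows the four-state rule with
pseudogene precedence: ≥ 1 LOF event → `pseudogene` (regardless of
completeness); complete without LOF → `gene`; incomplete and < 30 bp from a
contig border → `edge`; otherwise `truncated`.

Family assignment is BLASTX-style best-hit against a labelled panel that
includes decoy GPCRs (best-scoring decoy → discard); calls whose top two
bit scores differ by < 5 bits are flagged ambiguous. Tree-based curation by
visual inspection is replaced by a deterministic neighbour-joining
placement: a candidate is retained iff its nearest panel leaf is olfactory.
Exact nucleotide duplicates within a genome are collapsed to the first
locus in (contig, start) order.

# Reconciliation and rates

Gene-tree nodes with numeric support strictly below 90 are contracted;
nodes without a support value are treated as resolved. Reconciliation is
duplication–loss parsimony under the LCA mapping. Losses are placed on
explicit species branches by the path rule (a lineage passing a speciation
node without splitting loses a copy on the branch to the other child);
duplications are attributed to the branch above their mapped node, root
mappings to a synthetic stem. Rooting and polytomy resolution minimise
duplications + losses exhaustively: every edge of the unrooted topology is
tried as a root, polytomies are resolved over all (2k−3)!! binary
arrangements while the total stays under a cap that covers 7-child
polytomies, and — a subtle but necessary case — the root is additionally
allowed *inside* each resolved polytomy by rooting "at" every node of
degree ≥ 4. Larger polytomies fall back to greedy deepest-LCA joining with
a warning. Optimality is property-tested against an enumeration oracle
(all rooted binary refinements via `phangorn::allTrees`, scored by an
independent ape-based cost function).

Families are reconciled as **one gene tree per family**: the simulator's
surviving root lineages are joined on a basal spine (the family's common
ancestor predates the species root, so spine nodes map to the root). This
matters for rate estimation — reconciling root lineages separately turns
"lost everywhere except one clade" into an unobservable origination below
the root, silently deleting losses; with the joined tree those absences
become explicit loss events.

Per branch, b = G/(N·t) and d = L/(N·t) with N the reconciliation-implied
copy number entering the branch and t the branch length in My; branches
with t < 2 My, the stem (t undefined), and branches with N = 0 are excluded
with a recorded reason. The family-level estimate is gene-time pooled
(ΣG / Σ N·t), with the per-branch arithmetic mean reported alongside.
Family origination is tabulated in its own `origins` column so that the
bookkeeping identity N_child = N_parent + G + origins − L holds on every
branch, reducing to the plain gain/loss identity wherever origins are zero
(all real branches, in the joined-tree default).

**Identifiability of rate recovery.** Events on lineages that leave no
sampled descendants are invisible to any reconciliation: a duplication
whose daughter dies out hides one gain *and* one-plus losses. The hidden
fraction grows with d × (tree depth). Measured on 20-taxon, 300-My
simulations, the pooled estimator recovers b essentially unbiasedly across
regimes, while d̂ is biased low by ~3% at d = 2.5e−4, ~9–14% at d = 5e−4,
and ~17% at d = 1e−3; at the empirical scale of fish receptor families
(~7e−3/My) the bias would far exceed any usable recovery tolerance. The
15%-recovery acceptance test therefore runs at b = 1e−3, d = 5e−4 — inside
the identifiable regime — and this limitation applies equally to rates
estimated from real data by this class of methods: they are apparent rates.

# Comparative statistics

PGLS fits y ~ x by GLS under C(λ): the Brownian covariance of the tree with
off-diagonal entries scaled by λ ∈ [0, 1]. λ is estimated by maximising the
profile log-likelihood with golden-section search (tolerance 1e−6) plus
explicit endpoint checks; the slope test uses t with n − 2 df and the
unbiased residual variance; R² is computed in the λ̂-whitened space against
the GLS intercept-only model. λ = 0 on an ultrametric tree reduces the fit
*exactly* to OLS (tested to 1e−10), and coefficients at fixed λ match a
direct matrix-inversion oracle to 1e−8. Counts are regressed untransformed;
no multiple-testing correction is applied (raw p-values are reported).

Phylogenetic signal uses the same machinery with an intercept-only design
and a likelihood-ratio test against λ = 0 referenced to χ²₁. Because λ = 0
is a boundary of the parameter space, the χ²₁ reference is conservative
(the LR statistic follows a mixture with a point mass at zero; measured
size ≈ 0.7% at nominal 5%, n = 100). The calibration test asserts the size
never exceeds nominal and that power against pure Brownian motion is
essentially 1 — a nominal-5%-size assertion would be wrong for this test
by construction.

# The synthetic world

* **Species trees** are pure-birth (Yule) topologies rescaled to the crown
  age. A coalescent generator was rejected: it concentrates near-zero
  terminal branches, unlike published chronograms, and with integer-valued
  traits the ±0.5 rounding noise then dwarfs the modelled covariance
  between near-identical sister tips, wrecking PGLS calibration for reasons
  that have nothing to do with the estimator (95.0% CI coverage with
  Gaussian residuals on either tree shape; 78% with rounding on coalescent
  trees; 94% with rounding on Yule trees).
* **Family histories** follow a linear birth–death process simulated by
  exact per-lineage next-event sampling (rates b·m and d·m per gene per My,
  m a per-branch multiplier); the full genealogy is retained, so every
  simulation provides its true gene trees, per-branch event lists and
  copy numbers, with the bookkeeping identity asserted everywhere. Gains
  stop at N = 0 (re-gain from extinction is undefined for a linear
  process). Default rates are the empirical per-family means
  (OR 0.0071/0.0071, TAAR 0.0101/0.0079, OlfC 0.0059/0.0069,
  ORA 0.0018/0.0047); root counts are 40/20/15/8 — ORA's 8 follows the
  reported ancestral repertoire, the others are round numbers chosen below
  the modern means so that default simulations drift rather than explode.
* **Shared rate heterogeneity**: one log-normal multiplier per branch
  (mean 1 on the natural scale) shared by OR/TAAR/OlfC, with ORA seeing
  m^0.25 — emulating episodes of expansion/contraction that move the three
  dynamic families together while ORA stays comparatively stable.
* **Genomes**: each tip copy becomes a locus. Sequences evolve along the
  genealogy by Jukes–Cantor substitutions (default 5e−4/site/My) with at
  least one substitution per genealogy branch (paralogs must be
  distinguishable or downstream dedup would merge them) and never creating
  stops outside injected lesions; the start codon and terminal stop are
  protected. OR loci are intronless; TAAR/OlfC/ORA carry 1–2 `GT..AG`
  introns at true codon boundaries. Pseudogenes get 1–3 lesions (premature
  stop or ±1 bp frameshift) in the CDS interior, > 30 bp from either end.
  Truncated loci lose 25–45% of one end mid-contig; edge loci lose 25–45%
  at a contig border placed 0–25 bp away, with the cut landing in exonic
  sequence so that incompleteness is attributable to the border (a cut
  inside an intron leaves an unalignable stub and makes the edge/truncated
  distinction ambiguous for any aligner). Loci sharing a contig are
  separated by ≥ 2 × flank of random intergenic sequence.
* **Lamellae**: lamellae = max(0, round(intercept + slope·genes + ε)) with
  ε Brownian on the tree (σ per √My). Defaults (intercept 2, slope 0.08,
  σ = 0.5) give repertoires of 100–400 genes organs of ~10–35 lamellae with
  realistic scatter. The integer floor binds when σ·√depth approaches the
  expected count, breaking Gaussianity; the PGLS calibration experiments
  therefore run where expected counts stay ≥ ~10, which is also the regime
  the flat/multilamellar dichotomy (flat iff ≤ 2 lamellae) makes
  biologically interesting.

What a green suite establishes: that every algorithmic stage is correct
against its oracle, that the chain recovers a known truth end-to-end at
realistic divergence (≤ 0.15), and that the statistics are calibrated where
their assumptions hold. What it does not establish: performance on real
assemblies (fragmentation, N runs, repeats, contamination), recovery at
empirical birth/death rates (see the identifiability analysis above), or
robustness to gene-tree estimation error, which the true-genealogy
simulations bypass by design.

# Numerical and degenerate-input choices

Seeds flow top-down (every simulator takes one; the CLI derives stage seeds
by small offsets), and identical seed + config yields byte-identical
outputs. Rooting/resolution ties break by (cost, duplications, losses,
enumeration order), making reconciliation deterministic. Degenerate inputs
fail loudly: empty query sets, unmapped gene-tree leaves, constant
predictors, zero-variance traits, negative rates or branch lengths; an
all-branches-excluded family yields an explicit NA ("undefined") rather
than zero. Polytomous species trees are rejected — the chronogram contract
is binary — and gene trees with fewer than three leaves skip the rooting
search.
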