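---
title: "Whole-genome relatedness, synteny and island screening for genome pairs"
author: "pairplasma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome relatedness, synteny and island screening for genome pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairplasma)
```

## The problem

Closely related, co-occurring prokaryotes — for example the uncultivated
acidophilic archaea that dominate acid-mine-drainage biofilms — often share
16S rRNA identities close to the species boundary, so ribosomal genes alone
cannot resolve how distinct the lineages really are. Whole-genome measures
fill the gap. This package implements the standard battery used for such
panels of draft genomes:

* **Orthology by reciprocal best hit (RBH).** Genes $x$ in genome $A$ and
  $y$ in genome $B$ are called orthologs when $y$ is $x$'s best qualifying
  hit against $B$'s proteome *and* $x$ is $y$'s best qualifying hit against
  $A$'s.
* **Average amino acid identity (AAI)**: the unweighted mean percent
  identity over RBH pairs. Roughly 95–96% AAI corresponds to the classical
  70% DNA–DNA hybridization species cut-off, so AAI locates genome pairs
  relative to the species boundary.
* **Ortholog fraction**: the number of RBH pairs divided by the mean of the
  two gene counts, $|P| / \frac{n_A + n_B}{2}$ — a size-normalized measure
  of shared gene content.
* **Synteny conservation**: the fraction of orthologs falling in collinear
  blocks (syntenous orthologs / shared orthologs), and the mean block
  length in genes. Gene-order decay is a second, partly independent clock.
* **Marker-gene completeness**: the percentage of a marker-family set with
  a qualifying homolog, to contextualize all of the above for draft
  assemblies.
* **Annotation screens**: the four-tier annotation-confidence classifier,
  approximate (Hamming-tolerant) motif scans such as the sulfocyanin motif
  FNFNGTS and the aerobic form II CODH active-site motif AYRGAGR, and the
  type I copper-site pattern (H…C…H…M) of cupredoxin-fold blue-copper
  proteins implicated in iron oxidation.
* **Genomic-island screening**: maximal runs of consecutive genes with no
  ortholog in any genome of a reference panel — the signature of a
  lineage-specific, possibly horizontally acquired cluster — annotated with
  GC-composition deviation and strand GC skew.

Every stage is exercisable on simulated genome pairs with recorded ground
truth, so the whole pipeline is testable without downloading anything.

## Ortholog calling and its thresholds

Published comparative analyses frequently leave the ortholog-calling
recipe underspecified; reciprocal best hit is the minimal, widely used
operationalization, and every threshold here is explicit and configurable:

| parameter | default | meaning |
|---|---|---|
| `evalue_max` | 1e-5 | maximum e-value for a qualifying hit |
| `cov_min` | 0.7 | minimum aligned coverage of the *shorter* sequence |
| `pident_min` | 0 | minimum percent identity |

"Best" is the maximum bit score, with ties broken by percent identity and
then lexicographically by subject id, so ortholog maps are fully
deterministic. Hits come either from the internal aligner —
Smith–Waterman via `Biostrings::pairwiseAlignment` with BLOSUM62, gap open
11, extend 1, with bit scores and e-values from the Karlin–Altschul
transform using the standard gapped BLOSUM62 constants
($\lambda = 0.267$, $K = 0.041$), intended for desk-scale inputs — or from
precomputed BLAST-style 12-column tabular files via `read_hit_table()`,
which is the expected route for full proteomes. A fast score-only pass
computes the all-vs-all score matrix and full tracebacks are only done for
pairs passing the e-value filter.

Percent identity counts matches over all alignment columns (gap columns in
the denominator); `X` residues never count as matches and are scored as
mismatches, since draft genomes contain ambiguity.

## Nucleotide identity

`nucleotide_identity()` performs ends-free global alignment (match +1,
mismatch −1, gap open 5, extend 2) and reports matches over alignment
columns *excluding terminal overhangs*. Gene-boundary calls differ between
independently annotated genomes, so flanking overhangs are annotation
noise, not divergence; internal gaps still count. Plain end-charged global
alignment was rejected because co-optimal alignments can absorb chance
flank matches into the identity span.

## Synteny blocks

A block is a maximal run of ortholog pairs whose ordinals strictly
increase along genome A and strictly increase (orientation `same`) or
decrease (`inverted`) along genome B, with at most `gap_tolerance`
intervening genes between consecutive members on each genome, never
spanning a contig. Defaults — `gap_tolerance = 1`, `min_block_size = 2`,
inversions allowed — mirror common collinearity practice; published
"syntenous ortholog" counts are sensitive to these knobs, which is exactly
why they are exposed. Gene strand is deliberately ignored: order is the
signal, and block orientation is derived from ordinal direction.

Construction is greedy left-to-right with a deterministic tie-break
(extend with the smallest A-ordinal candidate first). At
`gap_tolerance = 0` the b-ordinals of ortholog pairs are unique, maximal
chains are connected components of the unique successor links, and the
greedy result is provably identical to exhaustive enumeration; the test
suite verifies this against an independent enumerator over *all* gene-order
permutations up to 8 genes, and checks maximality and disjointness
directly at positive gap tolerances.

## Tiered annotation confidence

The four tiers combine domain-database and nr-style evidence:

* **specific** — a specific-function domain hit with e-value ≤ 1e-10 and
  coverage > 70%;
* **putative** — a domain hit with e-value ≤ 1e-4 and coverage ≥ 50% that
  falls short of specific, or a general-function domain hit that would
  otherwise be specific;
* **probable** — an nr hit with > 30% identity over > 70% coverage;
* **hypothetical** — anything else.

The curation scheme this follows describes the putative tier as an
e-value *window* (between 1e-4 and 1e-10, 50–70% coverage). Read
literally, a window is non-monotone: improving a putative hit's e-value to
1e-12 at 60% coverage would disqualify it from every tier. The classifier
therefore reads each tier as "evidence at least this strong, short of the
next tier", which preserves the worked examples and guarantees that
strengthening evidence never lowers the tier — a property the test suite
checks on randomized evidence sets.

## The genome-pair evolver

`evolve_pair()` generates an ancestor of `n_genes` random proteins
(uniform residue usage; lengths geometric around `mean_protein_len` with a
50-residue floor, avoiding degenerate ultra-short alignments) and lets two
lineages diverge independently:

1. **Substitutions** — each site mutates with probability
   `sub_proportion`; replacements are uniform over the other 19 residues.
   Two lineages at per-site proportion $s$ give an expected pairwise
   identity of $100\,(1-s)^2$ (the $s^2/19$ back-mutation term is
   negligible at the regimes used). Substitutions are deliberately
   uniform — the pipeline measures identity, not evolutionary distance — a
   rate-matrix mutator is a documented extension point.
2. **Gene loss and gain** — per-gene Bernoulli loss, plus novel random
   genes inserted at random positions.
3. **Rearrangement** — `n_inversions` reversals and `n_translocations`
   interval moves of the gene order, applied to each lineage.
4. **Island insertion** — optionally, a contiguous block of novel genes
   whose DNA targets a GC content shifted by `gc_shift_sd` background
   standard deviations.

DNA is produced by reverse-translating each protein with codon choice
weighted by $p^{g}(1-p)^{3-g}$ ($g$ = GC count of the codon), where $p$ is
calibrated by root-finding so the expected GC matches the target; genes
are laid on contigs with fixed 30-bp spacers and random strands, minus
strand genes embedded reverse-complemented. A single seed governs all
randomness, and the same seed reproduces the simulation byte for byte.

The recorded truth — ancestor-mediated ortholog pairs with realized
identities, maximal collinear segments of the final orders, island
intervals, and every loss/gain — lets each statistic be validated against
a known answer. What the simulation does *not* emulate: within-gene
indels, codon-level selection, rate heterogeneity across sites or genes,
paralogous gene families, and shared ancestral repeats. Passing tests
therefore demonstrate correctness of the *statistics* under a clean
divergence model, not robustness to every artifact of real draft genomes;
on real data the RBH coverage threshold and the configurable synteny gaps
carry that load.

## Validation experiments and problem sizes

The shipped acceptance suite (also re-runnable via
`scripts/acceptance.R`) uses these designs, chosen to isolate one process
per experiment:

* **Zero-divergence limit** (30 genes, 2 contigs): AAI exactly 100,
  ortholog and synteny fractions exactly 1, one block per contig.
* **Divergence recovery**: per-lineage $s = 0.09$, 120 genes of mean
  length 500 (> 50,000 ortholog residues), pipeline AAI within ±1 point of
  the analytic 82.8%. Local-alignment end trimming biases AAI upward by
  roughly +0.1, well inside the band.
* **Ranking**: a four-level divergence ladder ($s$ = 0.02, 0.05, 0.09,
  0.14) must give Spearman $\rho = -1$ between substitution load and AAI;
  20 paired-seed replicates per inversion count (0–16) must give a
  non-increasing median mean block length. Paired seeds isolate the
  inversion effect from ancestor resampling.
* **Island recovery**: 200 replicates of a 9-gene island at +3 sd GC shift
  in a 60-gene genome, with light gene-content noise (loss 0.01) and no
  gains — gained genes are themselves lineage-specific and would conflate
  two event types — must be recovered with exact boundaries in ≥ 95% of
  replicates. A 1000-draw Monte Carlo of background pseudo-islands checks
  that $|z_{GC}| < 2$ in ≥ 90% of draws (concatenating 9 genes averages
  the per-gene distribution, so the calibration is conservative by
  design).

## Worked example

```{r example, eval = FALSE}
sim <- evolve_pair(evolver_params(n_genes = 60, mean_protein_len = 150,
                                  sub_proportion = 0.05, seed = 1))
hits_ab <- align_all_vs_all(sim$genome_a$proteins, sim$genome_b$proteins)
hits_ba <- align_all_vs_all(sim$genome_b$proteins, sim$genome_a$proteins)
om <- call_rbh(hits_ab, hits_ba, "A", "B",
               n_genes(sim$genome_a), n_genes(sim$genome_b))
compute_aai(om)                 # 90.86, near the analytic 100*(1-0.05)^2
blocks <- find_synteny_blocks(om, sim$genome_a, sim$genome_b)
synteny_metrics(blocks, om)
```

For multi-genome panels, `run_panel()` orchestrates every pair from one
declarative config (all thresholds explicit, no hidden defaults), writes
one TSV per statistic plus JSON run metadata, and resumes interrupted runs
from cached per-pair ortholog tables.

## Known limitations

* The internal aligner is exact Smith–Waterman without heuristic seeding;
  it is meant for simulated or reduced inputs (up to a few thousand
  proteins in total). Real proteome panels should be aligned externally
  and imported as tabular hits.
* RBH cannot represent one-to-many orthology; lineage-specific expansions
  appear as a single pair plus apparent gene gain.
* Island screening keys only on ortholog absence plus composition; it does
  not use codon usage, tetranucleotide signatures, or phylogenetic
  incongruence, and a like-composition donor leaves no compositional
  anomaly at all — absence across the panel is then the only signal, which
  is precisely why both GC deviation and GC skew are reported but neither
  is used as a filter.
* Completeness is a marker-presence fraction: 100% does not imply a closed
  genome, and the marker set is user-supplied by design.
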