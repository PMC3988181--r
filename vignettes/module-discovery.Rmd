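---
title: "Discovering functional modules in gene co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering functional modules in gene co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

coexmod implements a non-targeted pipeline for finding functionally
coherent gene sets — the motivating case being plant cell-wall
biosynthesis modules in a poplar expression compendium — from a
genome-wide co-expression network. This vignette explains the model
behind each stage, the tunable parameters and their defaults, the
synthetic-data generator used for validation, and the numerical and
design choices that were genuinely open.

## The pipeline at a glance

1. **Preprocessing** — map array probe sets to genes and screen outlier
   arrays (`map_probe_sets()`, `flag_outlier_arrays()`).
2. **Network construction** — sample redundancy weights, weighted
   Pearson correlations, a density scan over candidate cutoffs, and the
   thresholded network (`sample_weights()`, `weighted_cor_matrix()`,
   `density_scan()`, `select_cutoff()`, `build_network()`).
3. **Topology diagnostics** — degree distribution and power-law fit,
   clustering coefficients and their random-graph baseline
   (`topology_report()`).
4. **Module detection** — modularity maximization by recursive spectral
   bisection with Kernighan–Lin refinement (`detect_modules()`).
5. **GO enrichment** — per-module hypergeometric tests with Bonferroni
   and Benjamini–Hochberg correction, plus keyword-based module
   selection (`enrich_modules()`, `select_modules_by_terms()`).
6. **Promoter motifs** — 2,000-bp promoter extraction and exhaustive
   mismatch-tolerant k-mer overrepresentation with catalog matching
   (`extract_promoters()`, `discover_motifs()`, `match_catalog()`).

`run_pipeline()` orchestrates the stages; every stage is also usable on
its own. All randomness flows from one root seed through named
per-stage substreams, so disabling one stage never perturbs another.

## Sample redundancy weights and weighted correlation

Public compendia contain near-duplicate arrays — replicate
hybridizations, resubmissions of the same series — which, left alone,
let a single biological condition dominate every gene–gene correlation.
Each sample therefore receives a weight

$$w_s = \frac{1}{\sum_t \max(0, r_{st})^2},$$

where $r_{st}$ is the Pearson correlation between sample columns $s$
and $t$, the sum including $t = s$. Exact duplicates appearing $d$
times each receive weight $1/d$; a sample with no positively correlated
partner keeps weight 1. Squaring makes the penalty specific to strong
redundancy rather than broad weak similarity; only positive
correlations penalize because anti-correlated conditions are
informative, not redundant. Gene–gene similarity is then the weighted
Pearson correlation with these sample weights. With uniform weights it
reduces exactly to ordinary Pearson (tested to 1e-12), and the test
suite verifies that duplicating a sample and re-weighting brings the
correlation matrix closer to the unduplicated truth than ignoring the
duplication does.

Zero-variance sample columns get weight 1 with a warning (their
correlations are treated as 0); gene pairs with zero weighted variance
are undefined and skipped with a warning.

## Choosing the correlation cutoff

The network keeps edges with weighted correlation $r \ge c$ (positive
correlations only by default; `absolute = TRUE` thresholds on $|r|$).
The cutoff $c$ is selected from the density of the retained network,
$2E/(N(N-1))$ over the $N$ genes keeping at least one edge: as $c$
rises the curve first falls (weak links die faster than nodes drop
out), reaches an interior minimum, then rises again as only densely
inter-correlated groups survive. Following the established heuristic
for co-expression networks, the cutoff is set just above the density
minimum: argmin + offset, with offset 0.05 (on the reference poplar
compendium the minimum sits near 0.65 and the network is built at
0.70). Two numerical details:

* grid points whose network is degenerate (fewer than two connected
  nodes) are ignored when locating the minimum — past the maximum
  pairwise correlation the density is formally zero but meaningless;
* ties at the minimum resolve to the smallest cutoff, with a message.

The default grid is 0.05–0.95 in steps of 0.05.

## Module detection

Modules are found by maximizing Newman modularity

$$Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_ik_j}{2m}\right]\delta(c_i, c_j)$$

on the unweighted thresholded network. Each connected component is
recursively bisected by the sign pattern of the leading eigenvector of
the generalized modularity matrix $B^{(g)} = B_{g} -
\mathrm{diag}(\sum_{j \in g} B_{ij})$, each split is polished by
Kernighan–Lin single-node flips with best-prefix rollback, and
recursion continues while the best split raises $Q$ by at least
`min_delta_q` (default 1e-6, the stand-in for the original algorithm's
statistical stopping rule — a documented divergence, since that rule's
internals are not reproducible from the published description). A final
global refinement pass moves single nodes between neighboring modules
to a local maximum of $Q$. Components up to `dense_limit` (default
2000) nodes use a dense symmetric eigensolver, which is deterministic;
larger components fall back to seeded power iteration on the implicitly
shifted matrix.

Conventions: module ids are dense integers ordered by decreasing size,
so module 1 is always the largest; nodes left alone in a module after
refinement are reported as `unassigned` (modules have at least two
members, matching the reference study, whose partition likewise leaves
a small set of nodes outside modules); the returned `q` always equals
`modularity_q()` recomputed on the assignment (tested to 1e-12, and
cross-checked against igraph's independent modularity implementation).

## GO enrichment

For a module with $n$ annotated members in an annotated background of
$N$ genes, a term carried by $K$ background genes and $k$ module genes
scores the hypergeometric upper tail $P(X \ge k)$, evaluated through
the log-scale distribution function for stable extreme tails. The
conventions follow set-enrichment practice with a custom reference:

* the background $N$ is the number of distinct annotated genes
  genome-wide, and only annotated module members count toward $n$ —
  unannotated genes neither help nor hurt;
* each module tests the terms annotated in at least one of its members
  (the annotation table is taken as already propagated, as standard
  plant GO exports are; no GO-graph traversal);
* Bonferroni multiplies by the number of terms tested in that module,
  capped at 1; BH-FDR is computed per module over the same term set.

Both corrections are reported because the reference analysis describes
a Bonferroni correction yet quotes FDR values; module selection
(`enriched_modules()`, `select_modules_by_terms()`) uses BH-FDR < 0.05
to match the reported results. Modules need at least
`min_module_size = 3` annotated members to be tested.

## Promoter motif overrepresentation

The promoter is the up-to-2,000-bp window upstream of the translation
start (CDS start), strand-corrected and truncated at contig boundaries
with a warning. Instead of a suffix-tree motif discoverer plus a PWM
enrichment step, the package enumerates *all* $4^k$ candidate motifs
($k \in \{6, 8\}$ — 4,096 and 65,536 candidates, tractable by
position-marginal counting without per-motif neighborhood scans) and
counts mismatch-tolerant occurrences — Hamming distance at most 1 for
6-mers and 2 for 8-mers, the "small" analysis convention — in the
foreground (module promoters) and background (all other promoters of
the same genome by default). Windows containing N never match;
overlapping occurrences all count. Significance is the upper-tail
binomial probability of the foreground count given the background
per-window rate; surviving motifs are ranked by
$\log_2$ odds of foreground over background rate (pseudo-rate
$0.5/\text{bg windows}$ guards empty backgrounds) and truncated to
`top`.

Because 4,096 candidates are tested at once, the default filter
Bonferroni-adjusts the binomial p before comparing to `alpha`
(`correct = "none"` restores a raw-p filter). Under a null with no
planted motif, the Bonferroni filter reports essentially nothing, which
is the behavior a practitioner needs from an exhaustive scan.

Catalog matching compares each reported motif (and, by default, its
reverse complement — cis-elements are double-stranded) against IUPAC
consensus strings by ungapped alignment with the shorter sequence fully
inside the longer, counting positions whose base falls outside the
consensus class; the mismatch caps are again 1 (6-mers) and 2
(8-mers).

**Power is the known limitation of this stage.** Mismatch-tolerant
counting spreads a planted 6-mer's signal over its 19-motif Hamming
neighborhood, whose background rate is $19/4^6$ per window. With 50
foreground promoters of 2,000 bp and single insertions in ~80% of them,
the planted family's enrichment z-score is about 4–6 while the largest
of 4,096 null z-scores is about 3.5, so the planted motif (or a 1-
mismatch neighbor) lands in the top 3 in roughly 80–90% of simulated
studies rather than always. Stronger planting, shorter promoters or
larger modules push recovery to 1; the acceptance suite deliberately
keeps the harder conditions.

## The synthetic-data generator

`syn_config()` describes a synthetic study; its defaults are the
reference conditions used by the tests: 2,000 genes, 120 samples over
four tissues of 30, three planted modules of 50 genes, four redundant
sample triples, three GO terms planted at rate 0.8 over a background
rate of 0.05 plus two unplanted terms, and the consensus ACCCCC
inserted into module 1's promoters at rate 0.8 with 5% per-base
mutation.

* **Expression** follows a one-factor model per module:
  $x_{gs} = \lambda_g f_{ms} + \varepsilon_{gs}$ with loadings
  $\lambda_g \sim U(0.7, 1)$ (one random sign per module) and noise
  $\sigma = 0.4$, giving planted correlations near 0.8 — above typical
  network cutoffs, which is the point of bounding loadings away from
  zero. Background genes are independent unit-variance noise (scale is
  irrelevant to correlations). Per-tissue mean shifts apply to planted
  module genes; redundant samples are copies of a base sample with
  jitter at 5% of the gene's noise sd, small enough to be true
  redundancy but large enough that redundancy weighting is measurable.
* **Annotation** draws term membership independently per gene at the
  background or planted rate.
* **Genome** builds one contig per gene (promoter then CDS, strand
  chosen per gene), which avoids overlapping-promoter corner cases in
  the generator itself; the extractor still handles truncation and
  missing CDS records. On minus-strand genes the contig stores the
  reverse complement, so promoter extraction must (and does) read the
  reverse complement of the bases 3' of the CDS end.

What the generator does *not* emulate: probe-level array artifacts
(background, saturation, normalization residue), correlated background
genes, GO-term dependence, promoter sequence composition bias, and
multiple or variant motif insertions. Passing tests therefore
demonstrate the pipeline's statistical machinery, not robustness to
every artifact of real compendia.

## Judging module recovery

End-to-end recovery is scored by the adjusted Rand index between
detected and planted labels over assigned nodes *belonging to planted
modules*. At the density-selected cutoff the synthetic network — like
the reference network, more than half of whose modules have exactly two
nodes — retains a tail of background genes that pair into tiny modules.
Those genes have no ground-truth module (they are mutually independent
by construction), so including them under a single catch-all label
would measure the size of that tail, not recovery of the planted
modules. The strict all-assigned-nodes ARI is still reported by the
acceptance script for transparency.

## Problem sizes

The shipped validation uses the 2,000-gene reference study for the
end-to-end run, 20 independent 2,000-gene genomes for motif recovery,
50 replicates of an 800-gene null annotation for calibration of the
hypergeometric test, and exhaustive small-N sweeps (all hypergeometric
parameter tuples with N ≤ 30; 50 random graphs with ≤ 30 nodes for the
modularity oracle). These sizes were chosen so the whole suite runs on
a laptop in minutes while every statistical assertion retains a
3-standard-deviation margin.
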