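# coexmod

Non-targeted discovery of functionally coherent gene modules in
genome-wide co-expression networks — the motivating application being
the search for plant cell-wall biosynthesis genes in a poplar
microarray compendium. Starting from a normalized expression matrix,
the package builds a weighted-correlation network, detects modules by
modularity maximization, annotates them by GO term enrichment, and
tests whether a module's genes share overrepresented promoter
cis-regulatory elements. A synthetic-data generator with planted
modules, annotations and motifs makes every stage testable offline.

## The method

**Network.** Sample redundancy in public compendia is downweighted by
w_s = 1 / Σ_t max(0, r_st)², where r_st is the correlation between
sample columns (so d exact duplicates each weigh 1/d), and gene
similarity is the weighted Pearson correlation

r_gh = Σ w_s (x_gs − m_g)(x_hs − m_h) / √(Σ w_s (x_gs − m_g)² · Σ w_s (x_hs − m_h)²).

Edges keep pairs with r ≥ c; the cutoff c is chosen from the density
curve of the thresholded network (density falls, reaches an interior
minimum, rises again) as argmin + 0.05.

**Modules.** Newman modularity
Q = (1/2m) Σ_ij [A_ij − k_i k_j / 2m] δ(c_i, c_j)
is maximized by recursive spectral bisection of the (generalized)
modularity matrix with Kernighan–Lin refinement and a global
single-node-move pass. Module ids are ordered by decreasing size.

**Annotation.** Each module's GO terms are scored by the
hypergeometric upper tail P(X ≥ k) against the genome-wide annotated
background, with per-module Bonferroni and BH-FDR corrections; modules
are selected by keyword match among significant terms (e.g. "cell
wall").

**Promoter motifs.** For the selected modules, all 4^k candidate
k-mers (k = 6, 8) are counted in 2,000-bp promoters with mismatch
tolerance (1 for 6-mers, 2 for 8-mers), scored by a binomial
upper tail against the background promoter rate, ranked by log-odds,
and matched against an IUPAC consensus catalog of known
cis-regulatory elements.

## Worked example

A synthetic study with two planted 40-gene modules among 500 genes, a
planted GO term, and the consensus ACCCCC inserted into module 1's
promoters:

```r
library(coexmod)

cfg <- pipeline_config(
  syn = syn_config(
    n_genes = 500, n_samples = 60,
    modules = list(list(size = 40, factor_sd = 1, noise_sd = 0.4),
                   list(size = 40, factor_sd = 1, noise_sd = 0.4)),
    n_redundant_groups = 2, redundancy_size = 3,
    tissues = list(list(name = "leaf",  n = 30, shift = c(0.8, 0)),
                   list(name = "xylem", n = 30, shift = c(0, 0.8))),
    go_terms = data.frame(
      accession = c("GO:0009834", "GO:0015979"),
      name = c("secondary cell wall biogenesis", "photosynthesis"),
      background_rate = c(0.05, 0.10),
      planted_module = c(1, NA),
      planted_rate = c(0.8, 0)),
    motif = list(consensus = "ACCCCC", planted_module = 1,
                 insertion_rate = 0.8, mutation_prob = 0.05),
    promoter_len = 1000, seed = 7),
  out_dir = "demo-out", seed = 7)

res <- run_pipeline(cfg)
#> [input] simulated 500 genes x 60 samples
#> [preprocess] dropping 1 outlier array(s): s048_xylem
#> [netbuild] cutoff 0.40: 270 nodes, 1711 edges
#> [topology] mean degree 12.7, avg clustering 0.311 (random 0.047)
#> [moddetect] 64 modules, Q = 0.5659, 0 unassigned
#> [goenrich] 1 modules enriched (FDR < 0.05); 1 match keywords
#> [cisreg] module 1: 9 overrepresented motifs
#> [profiles] 270 genes x 2 tissues
```

The two largest detected modules are the planted ones (40 planted
genes plus a few correlated background genes each):

```r
print(res$partition)
#> Module partition: 64 modules, 270 assigned, 0 unassigned, Q = 0.5659
#>   module sizes: 44, 44, 15, 9, 7, 6, 5, 5, 4, 4, ...
```

The planted term tops module 1's enrichment table — 35 of its 37
annotated genes carry the term against 60 of the annotated background:

```r
head(as.data.frame(res$enrichment)[, c("module", "term_name", "k", "n",
                                       "K", "p_raw", "fdr_bh")], 3)
#>   module                      term_name  k  n  K        p_raw       fdr_bh
#> 1      1 secondary cell wall biogenesis 35 37 60 3.665826e-09 7.331651e-09
#> 2      1                 photosynthesis  3 37 48 1.000000e+00 1.000000e+00
#> 3      2                 photosynthesis  8 10 48 2.794019e-02 5.588039e-02
```

And the motif scan on module 1's promoters recovers the planted
consensus family — the top hit CCCCCC is a 1-mismatch neighbor of the
planted ACCCCC, whose Hamming-1 window counts it absorbs:

```r
res$motifs[["1"]][, c("motif", "fg_count", "bg_rate", "log_odds", "p_adj")]
#>    motif fg_count     bg_rate  log_odds        p_adj
#> 1 CCCCCC      330 0.004531429 0.7341561 3.089449e-14
#> 2 GCCCCC      283 0.004529225 0.5131940 3.413729e-05
#> 3 CCCCCA      275 0.004588733 0.4529919 1.599259e-03
#> ...
```

Every stage also writes its artifact (edge list, density scan, module
partition and per-module edges, enrichment table, motif report, tissue
profiles) as TSV under `out_dir`.

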