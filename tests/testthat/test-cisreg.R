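library(Biostrings)
library(GenomicRanges)

# hand-built two-contig genome with one gene per strand
toy_genome <- function() {
  set.seed(123)
  plus_seq <- paste(sample(c("A", "C", "G", "T"), 3500, TRUE),
                    collapse = "")
  minus_seq <- paste(sample(c("A", "C", "G", "T"), 3500, TRUE),
                     collapse = "")
  genome <- DNAStringSet(c(cplus = plus_seq, cminus = minus_seq))
  models <- GRanges(
    seqnames = c("cplus", "cminus"),
    ranges = IRanges(start = c(3000, 201), end = c(3299, 500)),
    strand = c("+", "-"))
  models$type <- "CDS"
  models$ID <- c("gplus", "gminus")
  list(genome = genome, models = models)
}

test_that("promoter extraction follows the strand and coordinate conventions", {
  toy <- toy_genome()
  prom <- extract_promoters(toy$genome, toy$models, length = 2000)
  # + strand, CDS start 3000: genomic 1000..2999
  expect_identical(unname(prom["gplus"]),
                   as.character(subseq(toy$genome[["cplus"]], 1000, 2999)))
  # - strand, CDS end 500: reverse complement of 501..2500
  expect_identical(unname(prom["gminus"]),
                   as.character(reverseComplement(
                     subseq(toy$genome[["cminus"]], 501, 2500))))
})

test_that("promoters truncate at contig boundaries with a warning", {
  toy <- toy_genome()
  short <- toy$models
  start(short)[1] <- 500; end(short)[1] <- 799   # CDS start 500
  expect_warning(prom <- extract_promoters(toy$genome, short,
                                           genes = "gplus",
                                           length = 2000),
                 "truncated")
  expect_identical(nchar(unname(prom["gplus"])), 499L)
})

test_that("genes without CDS records are skipped, not fatal", {
  toy <- toy_genome()
  expect_warning(prom <- extract_promoters(toy$genome, toy$models,
                                           genes = c("gplus", "ghost"),
                                           length = 100),
                 "skipped")
  expect_identical(attr(prom, "skipped"), "ghost")
  expect_identical(names(prom), "gplus")
})

test_that("k-mer counting obeys overlap and N-window semantics", {
  ps <- structure(c(p1 = "ACGTACGT"), class = "promoter_set")
  expect_identical(unname(count_kmer(ps, "ACGTAC", 0)), c(1L, 1L))
  aaa <- structure(c(p1 = "AAAAAAAA"), class = "promoter_set")
  expect_identical(unname(count_kmer(aaa, "AAAAAA", 0)), c(3L, 1L))
  withN <- structure(c(p1 = "AANAAAAAA"), class = "promoter_set")
  expect_identical(unname(count_kmer(withN, "AAAAAA", 0))[1], 1L)
  expect_error(count_kmer(ps, "ACGTAX", 0), "A,C,G,T")
})

test_that("k-mer counting matches the per-window Hamming oracle", {
  set.seed(99)
  seqs <- setNames(replicate(6, paste(
    sample(c("A", "C", "G", "T", "N"), 80, TRUE,
           prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")),
    paste0("p", 1:6))
  ps <- structure(seqs, class = "promoter_set")
  for (mm in 0:2) {
    got <- unname(count_kmer(ps, "ACGGTA", mm))
    expect_identical(got, as.integer(oracle_count_kmer(seqs, "ACGGTA", mm)))
  }
  # max_mm = k: every N-free window matches
  allw <- unname(count_kmer(ps, "ACGGTA", 6))
  expect_identical(allw, as.integer(oracle_count_kmer(seqs, "ACGGTA", 6)))
})

test_that("mismatch-tolerant count vectors equal neighbourhood enumeration", {
  set.seed(7)
  seqs <- replicate(4, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                             collapse = ""))
  names(seqs) <- paste0("s", 1:4)
  ps <- structure(seqs, class = "promoter_set")
  enc <- coexmod:::encode_windows(seqs, 6)
  counts <- coexmod:::exact_kmer_counts(enc, 6)
  tol1 <- coexmod:::mismatch_tolerant_counts(counts, 6, 1)
  # spot-check 25 random motifs against count_kmer (independent path)
  codes <- sample(0:(4^6 - 1), 25)
  for (cd in codes) {
    motif <- coexmod:::code_to_kmer(cd, 6)
    expect_identical(as.integer(tol1[cd + 1]),
                     unname(count_kmer(ps, motif, 1))[1])
  }
})

test_that("motif discovery recovers a planted consensus and honors alpha", {
  cfg <- tiny_syn_config(seed = 31, n_genes = 150,
                         modules = list(list(size = 50, factor_sd = 1,
                                             noise_sd = 0.4)),
                         tissues = list(), n_samples = 60,
                         go_terms = data.frame(),
                         motif = list(consensus = "ACCCCC",
                                      planted_module = 1,
                                      insertion_rate = 0.8,
                                      mutation_prob = 0.05),
                         promoter_len = 1000)
  gen <- simulate_genome(cfg)
  prom <- extract_promoters(gen$genome, gen$models,
                            length = cfg$promoter_len)
  labels <- planted_module_labels(cfg)
  fg <- prom[names(labels)[labels == 1]]
  bg <- prom[names(labels)[labels == 0]]
  res <- discover_motifs(fg, bg, k = 6)
  expect_gt(nrow(res), 0)
  neighbours <- vapply(res$motif, function(m)
    sum(strsplit(m, "")[[1]] != strsplit("ACCCCC", "")[[1]]) <= 1,
    logical(1))
  expect_true(any(neighbours[seq_len(min(3, nrow(res)))]))
  expect_identical(nrow(discover_motifs(fg, bg, k = 6, alpha = 0)), 0L)
  expect_error(discover_motifs(fg, fg, k = 6), "disjoint")
})

test_that("motif discovery is invariant to promoter order and gene relabeling", {
  set.seed(47)
  seqs <- setNames(replicate(30, paste(
    sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")),
    sprintf("g%02d", 1:30))
  fg <- structure(seqs[1:10], class = "promoter_set")
  bg <- structure(seqs[11:30], class = "promoter_set")
  r1 <- discover_motifs(fg, bg, k = 6, alpha = 1, top = 5)
  fg2 <- fg[sample(10)]
  names(fg2) <- sprintf("x%02d", 1:10)
  bg2 <- bg[sample(20)]
  r2 <- discover_motifs(fg2, bg2, k = 6, alpha = 1, top = 5)
  expect_identical(r1$motif, r2$motif)
  expect_equal(r1$p_enrich, r2$p_enrich, tolerance = 1e-12)
})

test_that("catalog matching applies IUPAC classes, containment and mismatch caps", {
  catalog <- data.frame(
    accession = c("S000288", "S000999", "SLONG"),
    consensus = c("GAGGGG", "ASGTAC", "TTGAGGGGTT"),
    description = c("SE1 stem element", "synthetic S-class entry",
                    "long consensus"),
    stringsAsFactors = FALSE)
  rep <- structure(data.frame(motif = c("GAGGGG", "ACGTAC", "CAGGGGGG"),
                              fg_count = 1, fg_seqs_with_hit = 1,
                              fg_windows = 10, bg_count = 0, bg_rate = 0,
                              log_odds = 1, p_enrich = 0.01, p_adj = 0.04,
                              stringsAsFactors = FALSE),
                   class = c("motif_report", "data.frame"))
  rep$matches <- replicate(3, NULL, simplify = FALSE)
  out <- match_catalog(rep, catalog, rc = FALSE)
  m1 <- out$matches[[1]]
  expect_identical(m1$accession[1], "S000288")
  expect_identical(m1$mismatches[1], 0L)
  # motif GAGGGG sits inside TTGAGGGGTT at 0 mismatches too
  expect_true("SLONG" %in% m1$accession)
  # IUPAC class: S = C or G, so ACGTAC matches ASGTAC at 0 mismatches
  m2 <- out$matches[[2]]
  expect_identical(m2$accession[1], "S000999")
  expect_identical(m2$mismatches[1], 0L)
  # 8-mer with no catalog entry within 2 mismatches stays unmatched
  m3 <- out$matches[[3]]
  expect_false("S000999" %in% m3$accession)
  bad <- data.frame(accession = "BAD", consensus = "ACZTAC",
                    description = "broken")
  expect_error(match_catalog(rep, bad), "BAD")
})

test_that("reverse-complement catalog matching is on by default", {
  catalog <- data.frame(accession = "RC1", consensus = "GGGGGT",
                        description = "rc target",
                        stringsAsFactors = FALSE)
  rep <- structure(data.frame(motif = "ACCCCC", fg_count = 1,
                              fg_seqs_with_hit = 1, fg_windows = 10,
                              bg_count = 0, bg_rate = 0, log_odds = 1,
                              p_enrich = 0.01, p_adj = 0.04,
                              stringsAsFactors = FALSE),
                   class = c("motif_report", "data.frame"))
  rep$matches <- list(NULL)
  out <- match_catalog(rep, catalog)
  expect_identical(out$matches[[1]]$accession, "RC1")
  out_f <- match_catalog(rep, catalog, rc = FALSE)
  # forward ACCCCC vs GGGGGT differs everywhere; only rc matches
  expect_identical(nrow(out_f$matches[[1]]), 0L)
})
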