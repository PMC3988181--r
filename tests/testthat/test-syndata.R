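test_that("noiseless single-factor module gives perfect pairwise correlation", {
  cfg <- syn_config(n_genes = 10, n_samples = 20,
                    modules = list(list(size = 10, factor_sd = 1,
                                        noise_sd = 0)),
                    n_redundant_groups = 0, redundancy_size = 1,
                    tissues = list(), go_terms = data.frame(),
                    motif = NULL, seed = 3)
  x <- simulate_expression(cfg)
  r <- abs(stats::cor(t(x)))
  expect_true(all(abs(r - 1) < 1e-12))
})

test_that("module-free expression has near-zero mean off-diagonal correlation", {
  cfg <- syn_config(n_genes = 60, n_samples = 200, modules = list(),
                    n_redundant_groups = 0, redundancy_size = 1,
                    tissues = list(), go_terms = data.frame(),
                    motif = NULL, seed = 11)
  x <- simulate_expression(cfg)
  r <- stats::cor(t(x))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.2)
})

test_that("all three generators are deterministic for a fixed seed", {
  cfg <- tiny_syn_config(seed = 5)
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$motif_truth, g2$motif_truth)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(syn_config(n_genes = 50,
                          modules = list(list(size = 60, factor_sd = 1,
                                              noise_sd = 0.1)),
                          tissues = list(), n_samples = 10,
                          n_redundant_groups = 0, go_terms = data.frame(),
                          motif = NULL),
               "modules")
  expect_error(tiny_syn_config(motif = list(consensus = "ACGTACG",
                                            planted_module = 1,
                                            insertion_rate = 0.5,
                                            mutation_prob = 0)),
               "motif")
  bad_go <- data.frame(accession = "GO:1", name = "x",
                       background_rate = 0.1, planted_module = 9,
                       planted_rate = 0.5)
  expect_error(tiny_syn_config(go_terms = bad_go), "go_terms")
})

test_that("degenerate annotation rates behave as specified", {
  cfg <- tiny_syn_config(go_terms = data.frame(
    accession = c("GO:A", "GO:B"), name = c("planted only", "everything"),
    background_rate = c(0, 1), planted_module = c(1, NA),
    planted_rate = c(1, 0)))
  ann <- simulate_annotation(cfg)
  labels <- planted_module_labels(cfg)
  a_genes <- sort(ann$gene_id[ann$term_accession == "GO:A"])
  expect_identical(a_genes, sort(names(labels)[labels == 1]))
  expect_setequal(ann$gene_id[ann$term_accession == "GO:B"], names(labels))
})

test_that("annotation counts are within 3 binomial SDs of expectation", {
  cfg <- syn_config(n_genes = 2000, n_samples = 10,
                    modules = list(list(size = 50, factor_sd = 1,
                                        noise_sd = 0.4)),
                    n_redundant_groups = 0, redundancy_size = 1,
                    tissues = list(),
                    go_terms = data.frame(accession = "GO:X", name = "x",
                                          background_rate = 0.05,
                                          planted_module = 1,
                                          planted_rate = 0.8),
                    motif = NULL, seed = 21)
  ann <- simulate_annotation(cfg)
  labels <- planted_module_labels(cfg)
  in_mod <- sum(ann$gene_id %in% names(labels)[labels == 1])
  in_bg <- nrow(ann) - in_mod
  expect_lt(abs(in_mod - 50 * 0.8), 3 * sqrt(50 * 0.8 * 0.2))
  expect_lt(abs(in_bg - 1950 * 0.05), 3 * sqrt(1950 * 0.05 * 0.95))
})

test_that("certain insertion without mutation plants the exact consensus", {
  cfg <- tiny_syn_config(motif = list(consensus = "ACCCCC",
                                      planted_module = 1,
                                      insertion_rate = 1,
                                      mutation_prob = 0))
  gen <- simulate_genome(cfg)
  prom <- extract_promoters(gen$genome, gen$models,
                            length = cfg$promoter_len)
  labels <- planted_module_labels(cfg)
  target <- names(labels)[labels == 1]
  expect_true(all(gen$motif_truth$inserted[gen$motif_truth$gene_id %in%
                                             target]))
  expect_true(all(grepl("ACCCCC", prom[target], fixed = TRUE)))
})

test_that("without insertion the consensus occurs at the background rate", {
  cfg <- syn_config(n_genes = 200, n_samples = 10,
                    modules = list(list(size = 50, factor_sd = 1,
                                        noise_sd = 0.4)),
                    n_redundant_groups = 0, redundancy_size = 1,
                    tissues = list(), go_terms = data.frame(),
                    motif = list(consensus = "ACCCCC", planted_module = 1,
                                 insertion_rate = 0, mutation_prob = 0),
                    promoter_len = 1000, cds_len = 60, seed = 9)
  gen <- simulate_genome(cfg)
  prom <- extract_promoters(gen$genome, gen$models,
                            length = cfg$promoter_len)
  n <- count_kmer(prom, "ACCCCC", max_mm = 0)[["occurrences"]]
  windows <- 200 * (1000 - 6 + 1)
  expected <- windows / 4^6
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})

test_that("minus-strand promoters are the reverse complement of the downstream genomic slice", {
  cfg <- tiny_syn_config(seed = 2)
  gen <- simulate_genome(cfg)
  cds <- gen$models[gen$models$type == "CDS"]
  minus <- as.character(cds$ID)[as.character(GenomicRanges::strand(cds)) == "-"]
  expect_gt(length(minus), 0)
  g <- minus[1]
  rec <- cds[cds$ID == g]
  e <- GenomicRanges::end(rec)
  slice <- Biostrings::subseq(gen$genome[[g]], e + 1,
                              e + cfg$promoter_len)
  prom <- extract_promoters(gen$genome, gen$models, genes = g,
                            length = cfg$promoter_len)
  expect_identical(unname(prom[g]),
                   as.character(Biostrings::reverseComplement(slice)))
})
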