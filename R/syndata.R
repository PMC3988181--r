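#' Configuration for the synthetic compendium generator
#'
#' Builds and validates the configuration driving the three synthetic-data
#' generators: a latent-factor expression matrix with planted co-expression
#' modules, a GO annotation table with terms enriched in planted modules,
#' and a genome (FASTA + GFF3) whose promoters carry a planted consensus
#' motif in one module's genes.
#'
#' The defaults describe the reference synthetic study used throughout the
#' package: 2,000 genes, 120 samples over four tissues, and three planted
#' modules of 50 genes each.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (columns).
#' @param modules List of planted modules, each a list with elements
#'   \code{size}, \code{factor_sd} and \code{noise_sd}. Module genes follow
#'   a one-factor model \eqn{x_{gs} = \lambda_g f_{ms} + \epsilon_{gs}} with
#'   \eqn{f_{ms} \sim N(0, factor\_sd)} and
#'   \eqn{\epsilon_{gs} \sim N(0, noise\_sd)}; loadings
#'   \eqn{\lambda_g \sim U(0.7, 1)} carry one random sign per module so
#'   planted correlations stay above typical network cutoffs.
#' @param n_redundant_groups Number of redundant sample groups; each group
#'   is one base sample plus near-identical copies, emulating replicate
#'   hybridizations in a public compendium.
#' @param redundancy_size Samples per redundant group (base + copies).
#' @param tissues List of tissues, each a list with \code{name}, \code{n}
#'   (sample count) and \code{shift} (numeric vector, one per-module mean
#'   shift applied to that module's genes in the tissue's samples).
#' @param go_terms Data frame with columns \code{accession}, \code{name},
#'   \code{background_rate}, \code{planted_module} (index or NA) and
#'   \code{planted_rate}.
#' @param motif List with \code{consensus} (6- or 8-mer over ACGT),
#'   \code{planted_module}, \code{insertion_rate}, \code{mutation_prob}.
#' @param promoter_len Promoter length in bases upstream of the CDS start.
#' @param cds_len Length of the simulated coding region per gene.
#' @param seed Root seed; each generator draws from its own named
#'   substream so stages remain independently reproducible.
#' @return A validated \code{syn_config} list.
#' @export
syn_config <- function(n_genes = 2000,
                       n_samples = 120,
                       modules = list(
                         list(size = 50, factor_sd = 1, noise_sd = 0.4),
                         list(size = 50, factor_sd = 1, noise_sd = 0.4),
                         list(size = 50, factor_sd = 1, noise_sd = 0.4)),
                       n_redundant_groups = 4,
                       redundancy_size = 3,
                       tissues = list(
                         list(name = "young_leaf", n = 30, shift = c(0.8, 0, 0)),
                         list(name = "mature_leaf", n = 30, shift = c(0, 0, 0)),
                         list(name = "root",       n = 30, shift = c(0, 0.8, 0)),
                         list(name = "xylem",      n = 30, shift = c(0, 0, 0.8))),
                       go_terms = data.frame(
                         accession = sprintf("GO:%07d", 1:5),
                         name = c("secondary cell wall biogenesis",
                                  "cellular glucan metabolic process",
                                  "cell wall organization",
                                  "photosynthesis",
                                  "protein phosphorylation"),
                         background_rate = c(0.05, 0.05, 0.05, 0.10, 0.15),
                         planted_module = c(1, 2, 3, NA, NA),
                         planted_rate = c(0.8, 0.8, 0.8, 0, 0)),
                       motif = list(consensus = "ACCCCC", planted_module = 1,
                                    insertion_rate = 0.8, mutation_prob = 0.05),
                       promoter_len = 2000,
                       cds_len = 300,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples, modules = modules,
              n_redundant_groups = n_redundant_groups,
              redundancy_size = redundancy_size, tissues = tissues,
              go_terms = go_terms, motif = motif,
              promoter_len = promoter_len, cds_len = cds_len, seed = seed)
  class(cfg) <- "syn_config"
  validate_syn_config(cfg)
}

validate_syn_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid syn_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_genes < 1) fail("n_genes", "must be positive")
  if (cfg$n_samples < 3) fail("n_samples", "need at least 3 samples")
  sizes <- vapply(cfg$modules, function(m) m$size, numeric(1))
  if (sum(sizes) > cfg$n_genes)
    fail("modules", "sum of module sizes exceeds n_genes")
  for (m in cfg$modules) {
    if (m$factor_sd < 0) fail("modules", "factor_sd must be >= 0")
    if (m$noise_sd < 0) fail("modules", "noise_sd must be >= 0")
  }
  if (length(cfg$tissues)) {
    tn <- sum(vapply(cfg$tissues, function(t) t$n, numeric(1)))
    if (tn != cfg$n_samples)
      fail("tissues", "tissue sample counts must sum to n_samples")
    for (t in cfg$tissues)
      if (length(t$shift) < length(cfg$modules))
        fail("tissues", "each tissue needs one shift per module")
  }
  if (cfg$n_redundant_groups * cfg$redundancy_size > cfg$n_samples)
    fail("n_redundant_groups", "redundant samples exceed n_samples")
  gt <- cfg$go_terms
  if (nrow(gt)) {
    if (any(gt$background_rate < 0 | gt$background_rate > 1))
      fail("go_terms", "background_rate outside [0,1]")
    if (any(gt$planted_rate < 0 | gt$planted_rate > 1))
      fail("go_terms", "planted_rate outside [0,1]")
    pm <- gt$planted_module
    if (any(!is.na(pm) & (pm < 1 | pm > length(cfg$modules))))
      fail("go_terms", "planted_module index out of range")
  }
  if (!is.null(cfg$motif)) {
    if (!nchar(cfg$motif$consensus) %in% c(6L, 8L))
      fail("motif", "consensus length must be 6 or 8")
    if (grepl("[^ACGT]", cfg$motif$consensus))
      fail("motif", "consensus must be over A,C,G,T")
    if (cfg$motif$insertion_rate < 0 || cfg$motif$insertion_rate > 1)
      fail("motif", "insertion_rate outside [0,1]")
    if (cfg$motif$mutation_prob < 0 || cfg$motif$mutation_prob > 1)
      fail("motif", "mutation_prob outside [0,1]")
    pm <- cfg$motif$planted_module
    if (pm < 1 || pm > length(cfg$modules))
      fail("motif", "planted_module index out of range")
  }
  if (cfg$promoter_len < 1) fail("promoter_len", "must be positive")
  cfg
}

syn_gene_ids <- function(cfg) sprintf("g%05d", seq_len(cfg$n_genes))

#' Planted module labels implied by a synthetic configuration
#'
#' Module m occupies a consecutive block of genes after the blocks of
#' modules 1..m-1; remaining genes are background (label 0).
#'
#' @param cfg A \code{\link{syn_config}}.
#' @return Named integer vector, gene id -> planted module (0 = background).
#' @export
planted_module_labels <- function(cfg) {
  labels <- integer(cfg$n_genes)
  at <- 1L
  for (m in seq_along(cfg$modules)) {
    sz <- cfg$modules[[m]]$size
    labels[at:(at + sz - 1L)] <- m
    at <- at + sz
  }
  names(labels) <- syn_gene_ids(cfg)
  labels
}

syn_sample_table <- function(cfg) {
  if (length(cfg$tissues)) {
    tissue <- unlist(lapply(cfg$tissues, function(t) rep(t$name, t$n)))
  } else {
    tissue <- rep("tissue1", cfg$n_samples)
  }
  data.frame(sample_id = sprintf("s%03d_%s", seq_len(cfg$n_samples), tissue),
             tissue = tissue, stringsAsFactors = FALSE)
}

#' Simulate a normalized expression matrix with planted modules
#'
#' Genes in planted module m follow a one-factor model; background genes are
#' independent Gaussian noise. Per-tissue mean shifts are added to planted
#' module genes, and redundant sample groups are created by copying a base
#' sample with small jitter (sd = 5% of the gene's noise sd), so that
#' redundancy weighting has a measurable effect downstream.
#'
#' @param cfg A \code{\link{syn_config}}.
#' @return Numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames. Attributes \code{planted_modules} (truth
#'   labels) and \code{tissue_of_sample} carry the ground truth.
#' @export
simulate_expression <- function(cfg) {
  cfg <- validate_syn_config(cfg)
  set.seed(derive_seed(cfg$seed, "expression"))
  genes <- syn_gene_ids(cfg)
  samples <- syn_sample_table(cfg)
  labels <- planted_module_labels(cfg)

  # per-gene residual noise sd: module noise_sd, 1 for background genes
  noise_sd <- ifelse(labels == 0, 1,
                     vapply(cfg$modules, function(m) m$noise_sd,
                            numeric(1))[pmax(labels, 1)])
  x <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes) * noise_sd

  for (m in seq_along(cfg$modules)) {
    mod <- cfg$modules[[m]]
    idx <- which(labels == m)
    sign_m <- sample(c(-1, 1), 1)
    lambda <- sign_m * stats::runif(length(idx), 0.7, 1.0)
    f <- stats::rnorm(cfg$n_samples, 0, mod$factor_sd)
    x[idx, ] <- x[idx, ] + outer(lambda, f)
  }

  if (length(cfg$tissues)) {
    for (m in seq_along(cfg$modules)) {
      idx <- which(labels == m)
      shift <- unlist(lapply(cfg$tissues,
                             function(t) rep(t$shift[m], t$n)))
      x[idx, ] <- sweep(x[idx, , drop = FALSE], 2, shift, "+")
    }
  }

  if (cfg$n_redundant_groups > 0 && cfg$redundancy_size > 1) {
    for (g in seq_len(cfg$n_redundant_groups)) {
      cols <- ((g - 1) * cfg$redundancy_size + 1):(g * cfg$redundancy_size)
      base <- cols[1]
      for (cc in cols[-1]) {
        x[, cc] <- x[, base] +
          stats::rnorm(cfg$n_genes, 0, 0.05 * noise_sd)
      }
    }
  }

  dimnames(x) <- list(genes, samples$sample_id)
  attr(x, "planted_modules") <- labels
  attr(x, "tissue_of_sample") <- stats::setNames(samples$tissue,
                                                 samples$sample_id)
  x
}

#' Simulate a GO annotation table with planted enrichment
#'
#' Each gene is annotated with a term with probability
#' \code{background_rate}, or \code{planted_rate} if the gene belongs to
#' the term's planted module.
#'
#' @param cfg A \code{\link{syn_config}}.
#' @param genes Gene ids; defaults to the configuration's gene ids and must
#'   match the expression generator's output.
#' @return Data frame with columns \code{gene_id}, \code{term_accession},
#'   \code{term_name}.
#' @export
simulate_annotation <- function(cfg, genes = syn_gene_ids(cfg)) {
  cfg <- validate_syn_config(cfg)
  set.seed(derive_seed(cfg$seed, "annotation"))
  labels <- planted_module_labels(cfg)[genes]
  labels[is.na(labels)] <- 0L
  out <- vector("list", nrow(cfg$go_terms))
  for (i in seq_len(nrow(cfg$go_terms))) {
    t <- cfg$go_terms[i, ]
    p <- rep(t$background_rate, length(genes))
    if (!is.na(t$planted_module))
      p[labels == t$planted_module] <- t$planted_rate
    hit <- stats::runif(length(genes)) < p
    out[[i]] <- data.frame(gene_id = genes[hit],
                           term_accession = t$accession,
                           term_name = t$name,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_motif <- function(consensus, mutation_prob) {
  bases <- strsplit(consensus, "")[[1]]
  flip <- stats::runif(length(bases)) < mutation_prob
  for (i in which(flip))
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  paste(bases, collapse = "")
}

#' Simulate a genome and gene models with a planted promoter motif
#'
#' Builds one contig per gene: a promoter of \code{promoter_len} random
#' bases followed by a CDS, laid out on a randomly chosen strand. For genes
#' of the motif's planted module the consensus is inserted (with per-base
#' mutation) at a uniform-random promoter position with probability
#' \code{insertion_rate}. On the minus strand the contig stores the reverse
#' complement, so the promoter occupies the bases immediately 3' of the CDS
#' end in genome coordinates.
#'
#' @param cfg A \code{\link{syn_config}}.
#' @param genes Gene ids (default: the configuration's).
#' @return List with \code{genome} (a \code{DNAStringSet}), \code{models}
#'   (a \code{GRanges} with gene and CDS records, 1-based inclusive), and
#'   \code{motif_truth} (data frame: gene_id, inserted, position of the
#'   insertion within the promoter, NA when absent).
#' @export
simulate_genome <- function(cfg, genes = syn_gene_ids(cfg)) {
  cfg <- validate_syn_config(cfg)
  set.seed(derive_seed(cfg$seed, "genome"))
  labels <- planted_module_labels(cfg)[genes]
  labels[is.na(labels)] <- 0L
  L <- cfg$promoter_len
  clen <- cfg$cds_len
  k <- if (is.null(cfg$motif)) 0L else nchar(cfg$motif$consensus)

  seqs <- character(length(genes))
  strand <- character(length(genes))
  cds_start <- integer(length(genes))
  cds_end <- integer(length(genes))
  inserted <- logical(length(genes))
  position <- rep(NA_integer_, length(genes))

  for (i in seq_along(genes)) {
    promoter <- random_dna(L)
    in_target <- !is.null(cfg$motif) &&
      labels[i] == cfg$motif$planted_module
    if (in_target && stats::runif(1) < cfg$motif$insertion_rate) {
      pos <- sample.int(L - k + 1L, 1)
      ins <- mutate_motif(cfg$motif$consensus, cfg$motif$mutation_prob)
      substr(promoter, pos, pos + k - 1L) <- ins
      inserted[i] <- TRUE
      position[i] <- pos
    }
    cds <- paste0("ATG", random_dna(clen - 3L))
    strand[i] <- sample(c("+", "-"), 1)
    if (strand[i] == "+") {
      seqs[i] <- paste0(promoter, cds)
      cds_start[i] <- L + 1L
      cds_end[i] <- L + clen
    } else {
      seqs[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste0(promoter, cds))))
      cds_start[i] <- 1L
      cds_end[i] <- clen
    }
  }

  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, genes))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genes, each = 2),
    ranges = IRanges::IRanges(
      start = rep(cds_start, each = 2),
      end = rep(cds_end, each = 2)),
    strand = rep(strand, each = 2))
  gr$type <- rep(c("gene", "CDS"), length(genes))
  gr$ID <- rep(genes, each = 2)
  gr$phase <- rep(c(NA_integer_, 0L), length(genes))
  list(genome = genome,
       models = gr,
       motif_truth = data.frame(gene_id = genes, inserted = inserted,
                                position = position,
                                stringsAsFactors = FALSE))
}

#' Write synthetic inputs to disk in their interchange formats
#'
#' Expression as TSV (first column gene ids, header row sample ids),
#' annotation as TSV, genome as FASTA, gene models as GFF3, and truth
#' tables (module labels, motif insertions) as TSVs for validation.
#'
#' @param cfg A \code{\link{syn_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- simulate_expression(cfg)
  ann <- simulate_annotation(cfg)
  gen <- simulate_genome(cfg)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    genome = file.path(dir, "genome.fa"),
    models = file.path(dir, "models.gff3"),
    module_truth = file.path(dir, "module_truth.tsv"),
    motif_truth = file.path(dir, "motif_truth.tsv"),
    tissues = file.path(dir, "tissue_of_sample.tsv"))
  write_expression_matrix(x, paths$expression)
  write_tsv(ann, paths$annotation)
  Biostrings::writeXStringSet(gen$genome, paths$genome)
  rtracklayer::export(gen$models, paths$models, format = "gff3")
  labels <- attr(x, "planted_modules")
  write_tsv(data.frame(gene_id = names(labels), module = labels),
            paths$module_truth)
  write_tsv(gen$motif_truth, paths$motif_truth)
  tos <- attr(x, "tissue_of_sample")
  write_tsv(data.frame(sample_id = names(tos), tissue = tos), paths$tissues)
  invisible(paths)
}

#' Read / write an expression matrix TSV
#'
#' Layout: header row of sample ids, first column of gene ids.
#'
#' @param x Numeric matrix with dimnames.
#' @param path File path.
#' @return \code{read_expression_matrix} returns the numeric matrix.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
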