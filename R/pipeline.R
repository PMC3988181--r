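#' Tissue expression profiles as log ratios to the tissue mean
#'
#' For each gene, the per-tissue value is the mean signal over that
#' tissue's samples, and the reported value is
#' \code{log2(tissue value / mean of the per-tissue values)} — so a gene
#' expressed equally everywhere scores 0 in every tissue, and xylem-
#' preferential genes score positive in xylem.
#'
#' @param x Expression matrix (genes x samples); signals must be positive
#'   for the log ratio to be defined.
#' @param tissue_of_sample Named character vector mapping every sample id
#'   to a tissue.
#' @param genes Genes to report, in output row order (default all rows).
#' @return Numeric matrix (genes x tissues) of log2 ratios. Genes with a
#'   nonpositive tissue mean are dropped with a warning.
#' @export
tissue_profiles <- function(x, tissue_of_sample, genes = rownames(x)) {
  if (!all(colnames(x) %in% names(tissue_of_sample)))
    stop("every sample must be mapped to a tissue")
  genes <- intersect(genes, rownames(x))
  tissues <- unique(tissue_of_sample[colnames(x)])
  means <- sapply(tissues, function(t) {
    cols <- colnames(x)[tissue_of_sample[colnames(x)] == t]
    rowMeans(x[genes, cols, drop = FALSE])
  })
  if (length(genes) == 1)
    means <- matrix(means, nrow = 1,
                    dimnames = list(genes, tissues))
  bad <- apply(means, 1, function(v) any(v <= 0))
  if (any(bad)) {
    warning(sum(bad), " gene(s) with nonpositive tissue mean dropped")
    means <- means[!bad, , drop = FALSE]
  }
  log2(means / rowMeans(means))
}

#' Overlap statistics between two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return List with \code{n_common}, \code{pct_of_a}, \code{pct_of_b}
#'   (percentages rounded to one decimal; \code{NA} for an empty set).
#' @examples
#' # 20 genes shared by a 52-gene module and a published cluster -> 38.5%
#' overlap_stats(paste0("g", 1:52), paste0("g", 33:80))
#' @export
overlap_stats <- function(set_a, set_b) {
  common <- length(intersect(set_a, set_b))
  pct <- function(n) if (n == 0) NA_real_ else round(100 * common / n, 1)
  list(n_common = common,
       pct_of_a = pct(length(unique(set_a))),
       pct_of_b = pct(length(unique(set_b))))
}

#' Pipeline configuration
#'
#' Collects every tunable of the module-discovery pipeline in one
#' validated list. Stage toggles switch whole stages off; all randomness
#' flows from the root seed through per-stage substreams.
#'
#' @param syn A \code{\link{syn_config}} for synthetic input generation,
#'   or NULL when \code{paths} point at existing input files.
#' @param paths Named list of input paths (\code{expression},
#'   \code{annotation}, \code{genome}, \code{models}, \code{tissues});
#'   ignored when \code{syn} is given.
#' @param out_dir Output directory for all stage artifacts.
#' @param cutoffs Correlation cutoff grid for the density scan.
#' @param cutoff_offset Offset added to the density-minimum cutoff.
#' @param cutoff Fixed correlation cutoff; NA selects it from the scan.
#' @param min_module_size Minimum annotated module size for enrichment.
#' @param alpha_go FDR level for GO term significance.
#' @param alpha_motif Significance level for motif enrichment.
#' @param keywords Keywords selecting modules for the motif stage.
#' @param motif_k Motif lengths analyzed (subset of 6, 8).
#' @param min_delta_q Modularity gain threshold for module splitting.
#' @param stages Character vector of enabled stages, a subset of
#'   \code{c("topology", "goenrich", "cisreg", "profiles")}; the
#'   simulate/load, network and module stages always run.
#' @param seed Root seed.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(syn = syn_config(seed = seed),
                            paths = NULL,
                            out_dir = tempfile("coexmod"),
                            cutoffs = seq(0.05, 0.95, by = 0.05),
                            cutoff_offset = 0.05,
                            cutoff = NA_real_,
                            min_module_size = 3,
                            alpha_go = 0.05,
                            alpha_motif = 0.05,
                            keywords = c("cell wall"),
                            motif_k = 6,
                            min_delta_q = 1e-6,
                            stages = c("topology", "goenrich", "cisreg",
                                       "profiles"),
                            seed = 1) {
  cfg <- list(syn = syn, paths = paths, out_dir = out_dir,
              cutoffs = cutoffs, cutoff_offset = cutoff_offset,
              cutoff = cutoff, min_module_size = min_module_size,
              alpha_go = alpha_go, alpha_motif = alpha_motif,
              keywords = keywords, motif_k = motif_k,
              min_delta_q = min_delta_q, stages = stages, seed = seed)
  if (is.null(cfg$syn) && is.null(cfg$paths))
    stop("either syn or paths must be provided")
  if (!is.null(cfg$paths)) {
    need <- c("expression", "annotation")
    missing <- setdiff(need, names(cfg$paths))
    if (length(missing))
      stop("paths lacks: ", paste(missing, collapse = ", "))
    for (p in unlist(cfg$paths))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  bad <- setdiff(stages, c("topology", "goenrich", "cisreg", "profiles"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full module-discovery pipeline
#'
#' Executes the stages in order — simulate or load inputs, network
#' construction (sample weights, weighted correlations, density-guided
#' cutoff), topology diagnostics, module detection, GO enrichment,
#' keyword-based module selection, promoter motif discovery, and tissue
#' profiles — writing every intermediate to \code{out_dir} and logging
#' one line of counts per stage. Identical configuration and seed yield
#' identical outputs.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with all stage results: \code{expression},
#'   \code{weights}, \code{scan}, \code{cutoff}, \code{network},
#'   \code{topology}, \code{partition}, \code{enrichment},
#'   \code{selected_modules}, \code{motifs} (list per module),
#'   \code{profiles}, and \code{files}.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_line <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(files = character(0))

  # --- inputs ---------------------------------------------------------
  if (!is.null(cfg$syn)) {
    x <- simulate_expression(cfg$syn)
    ann <- simulate_annotation(cfg$syn)
    gen <- if ("cisreg" %in% cfg$stages) simulate_genome(cfg$syn) else NULL
    tissue_of_sample <- attr(x, "tissue_of_sample")
    log_line("[input] simulated %d genes x %d samples", nrow(x), ncol(x))
  } else {
    x <- read_expression_matrix(cfg$paths$expression)
    ann <- read_tsv(cfg$paths$annotation)
    gen <- NULL
    tissue_of_sample <- if (!is.null(cfg$paths$tissues)) {
      tt <- read_tsv(cfg$paths$tissues)
      stats::setNames(tt$tissue, tt$sample_id)
    } else NULL
    log_line("[input] loaded %d genes x %d samples", nrow(x), ncol(x))
  }
  # --- preprocess -----------------------------------------------------
  # probe-set mapping applies only to loaded platform data
  if (!is.null(cfg$paths$probe_hits)) {
    map <- map_probe_sets(read_tsv(cfg$paths$probe_hits), seed = cfg$seed)
    write_probe_gene_map(map, file.path(cfg$out_dir, "probe_gene_map.tsv"))
    keep <- intersect(rownames(x), unname(map$assignments))
    x <- x[keep, , drop = FALSE]
    log_line("[preprocess] %d probe sets assigned; %d genes retained",
             length(map$assignments), nrow(x))
  }
  flagged <- flag_outlier_arrays(x)
  if (length(flagged)) {
    log_line("[preprocess] dropping %d outlier array(s): %s",
             length(flagged), paste(flagged, collapse = ", "))
    x <- x[, setdiff(colnames(x), flagged), drop = FALSE]
  }
  res$expression <- x

  # --- network --------------------------------------------------------
  w <- sample_weights(x)
  r <- weighted_cor_matrix(x, w)
  scan <- density_scan(r, cutoffs = cfg$cutoffs, is_cor = TRUE)
  cutoff <- if (is.na(cfg$cutoff))
    select_cutoff(scan, cfg$cutoff_offset) else cfg$cutoff
  net <- build_network(r, cutoff = cutoff, is_cor = TRUE)
  res$weights <- w
  res$scan <- scan
  res$cutoff <- cutoff
  res$network <- net
  write_tsv(scan, file.path(cfg$out_dir, "density_scan.tsv"))
  write_edge_list(net, file.path(cfg$out_dir, "edges.tsv"))
  log_line("[netbuild] cutoff %.2f: %d nodes, %d edges", cutoff,
           length(net$nodes), nrow(net$edges))

  # --- topology -------------------------------------------------------
  if ("topology" %in% cfg$stages) {
    res$topology <- topology_report(net)
    write_topology_report(res$topology, cfg$out_dir)
    log_line("[topology] mean degree %.1f, avg clustering %.3f (random %.3f)",
             res$topology$mean_degree, res$topology$avg_clustering,
             res$topology$random_expected_c)
  }

  # --- modules --------------------------------------------------------
  part <- detect_modules(net, min_delta_q = cfg$min_delta_q,
                         seed = cfg$seed)
  res$partition <- part
  write_module_partition(part, net, cfg$out_dir)
  log_line("[moddetect] %d modules, Q = %.4f, %d unassigned",
           length(unique(part$assignment)), part$q,
           length(part$unassigned))

  # --- GO enrichment --------------------------------------------------
  if ("goenrich" %in% cfg$stages) {
    enr <- enrich_modules(part, ann,
                          min_module_size = cfg$min_module_size,
                          alpha = cfg$alpha_go)
    res$enrichment <- enr
    write_tsv(as.data.frame(enr), file.path(cfg$out_dir, "enrichment.tsv"))
    res$selected_modules <- select_modules_by_terms(enr, cfg$keywords,
                                                    cfg$alpha_go)
    log_line("[goenrich] %d modules enriched (FDR < %g); %d match keywords",
             length(enriched_modules(enr, cfg$alpha_go)), cfg$alpha_go,
             length(res$selected_modules))
  }

  # --- promoter motifs ------------------------------------------------
  if ("cisreg" %in% cfg$stages && !is.null(gen) &&
      length(res$selected_modules %||% integer(0))) {
    promoters <- extract_promoters(gen$genome, gen$models,
                                   length = cfg$syn$promoter_len)
    res$motifs <- list()
    for (mod in res$selected_modules) {
      fg_genes <- names(part$assignment)[part$assignment == mod]
      fg <- promoters[intersect(fg_genes, names(promoters))]
      bg <- promoters[setdiff(names(promoters), fg_genes)]
      reports <- lapply(cfg$motif_k, function(k)
        discover_motifs(fg, bg, k = k, alpha = cfg$alpha_motif))
      rep_k <- do.call(rbind, reports)
      res$motifs[[as.character(mod)]] <- rep_k
      log_line("[cisreg] module %d: %d overrepresented motifs", mod,
               nrow(rep_k))
    }
    write_motif_report(res$motifs,
                       file.path(cfg$out_dir, "motifs.tsv"))
  }

  # --- tissue profiles ------------------------------------------------
  if ("profiles" %in% cfg$stages && !is.null(tissue_of_sample)) {
    genes <- names(part$assignment)
    shifted <- x - min(x) + 1   # profiles need positive signal
    prof <- tissue_profiles(shifted, tissue_of_sample, genes)
    res$profiles <- prof
    write_tsv(data.frame(gene_id = rownames(prof), prof,
                         check.names = FALSE),
              file.path(cfg$out_dir, "tissue_profiles.tsv"))
    log_line("[profiles] %d genes x %d tissues", nrow(prof), ncol(prof))
  }

  invisible(res)
}
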