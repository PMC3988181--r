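#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least k term-annotated genes in a module of n genes sampled without
#' replacement from a genome of N genes of which K carry the term.
#' Evaluated through the log-scale distribution function for numerical
#' stability at extreme tails.
#'
#' @param k Observed annotated genes in the module.
#' @param n Annotated module size (draws).
#' @param K Genome-wide genes carrying the term.
#' @param N Genome-wide annotated background size.
#' @return The tail probability in [0, 1].
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0))
    stop("arguments must be non-negative")
  if (any(k > n) || any(n > N) || any(k > K) || any(K > N))
    stop("require 0 <= k <= n <= N and k <= K <= N")
  if (length(k) == 1 && k == 0) return(1)
  p <- exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                         log.p = TRUE))
  pmin(p, 1)
}

#' Per-module GO term enrichment
#'
#' Tests every term annotated in a module (at least \code{min_module_size}
#' annotated members) against the genome-wide annotated background by the
#' hypergeometric upper tail. Within each module, Bonferroni multiplies
#' the raw p by the number of terms tested in that module (capped at 1)
#' and Benjamini-Hochberg FDR is computed over the same term set. Only
#' annotated module members count toward the draw size n, so unannotated
#' genes neither help nor hurt.
#'
#' @param p A \code{module_partition} (or a named vector gene -> module).
#' @param ann Annotation data frame with columns \code{gene_id},
#'   \code{term_accession}, \code{term_name}.
#' @param min_module_size Minimum number of annotated module members.
#' @param alpha Significance level used by \code{\link{enriched_modules}}.
#' @return Object of class \code{enrichment_table}: data frame with
#'   columns module, term_accession, term_name, k, n, K, N, p_raw,
#'   p_bonferroni, fdr_bh; attribute \code{alpha} records the level.
#' @export
enrich_modules <- function(p, ann, min_module_size = 3, alpha = 0.05) {
  assignment <- if (inherits(p, "module_partition")) p$assignment else p
  if (!nrow(ann)) stop("annotation table is empty")
  ann <- unique(ann[, c("gene_id", "term_accession", "term_name")])
  background <- unique(ann$gene_id)
  N <- length(background)
  K_tab <- table(ann$term_accession)
  term_names <- ann$term_name[!duplicated(ann$term_accession)]
  names(term_names) <- ann$term_accession[!duplicated(ann$term_accession)]

  out <- list()
  for (mod in sort(unique(assignment))) {
    genes <- names(assignment)[assignment == mod]
    mod_ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
    n <- length(unique(mod_ann$gene_id))
    if (n < min_module_size) next
    k_tab <- table(mod_ann$term_accession)
    terms <- names(k_tab)
    k <- as.integer(k_tab)
    K <- as.integer(K_tab[terms])
    p_raw <- vapply(seq_along(terms), function(i)
      hypergeom_tail(k[i], n, K[i], N), numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      module = mod,
      term_accession = terms,
      term_name = unname(term_names[terms]),
      k = k, n = n, K = K, N = N,
      p_raw = p_raw,
      p_bonferroni = pmin(p_raw * length(terms), 1),
      fdr_bh = stats::p.adjust(p_raw, method = "BH"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    res <- data.frame(module = integer(0), term_accession = character(0),
                      term_name = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p_raw = numeric(0), p_bonferroni = numeric(0),
                      fdr_bh = numeric(0))
  else
    res <- do.call(rbind, out)
  res <- res[order(res$module, res$p_raw, res$term_accession), ]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_table", "data.frame"),
            alpha = alpha)
}

#' Modules identified by significant term enrichment
#'
#' A module counts as identified when at least one of its terms passes
#' the BH-FDR threshold.
#'
#' @param e An \code{enrichment_table}.
#' @param alpha FDR level (defaults to the table's recorded level).
#' @return Integer vector of module ids.
#' @export
enriched_modules <- function(e, alpha = attr(e, "alpha") %||% 0.05) {
  sort(unique(e$module[e$fdr_bh < alpha]))
}

#' Select modules whose significant terms match keywords
#'
#' Case-insensitive substring match of keywords against the names of
#' terms significant at the FDR level — e.g. keyword "cell wall" selects
#' modules enriched for "secondary cell wall biogenesis".
#'
#' @param e An \code{enrichment_table}.
#' @param keywords Character vector of keywords.
#' @param alpha FDR level.
#' @return Integer vector of module ids.
#' @export
select_modules_by_terms <- function(e, keywords,
                                    alpha = attr(e, "alpha") %||% 0.05) {
  if (!length(keywords)) stop("keywords must be non-empty")
  sig <- e[e$fdr_bh < alpha, , drop = FALSE]
  hit <- Reduce(`|`, lapply(keywords, function(kw)
    grepl(kw, sig$term_name, ignore.case = TRUE, fixed = FALSE)))
  if (is.null(hit)) return(integer(0))
  sort(unique(sig$module[hit]))
}

#' @export
print.enrichment_table <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  cat(sprintf("GO enrichment: %d tests across %d modules; %d modules with FDR < %g\n",
              nrow(x), length(unique(x$module)),
              length(enriched_modules(x, alpha)), alpha))
  NextMethod()
}
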