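#' Map probe sets to genes from a perfect-match hit table
#'
#' Applies the platform-annotation mapping rules used before network
#' construction. For each probe set, candidate genes are those hit by at
#' least four perfectly aligned probes ("more than three"). A probe set
#' with no candidate is unmapped; with a unique best candidate (most
#' perfect probes) it is assigned to that gene; a tie at the maximum count
#' removes the probe set as multi-mapping. Genes claimed by more than one
#' assigned probe set keep one set chosen uniformly at random under the
#' given seed; the rest are recorded as duplicate resolutions.
#'
#' @param hits Data frame with columns \code{probe_set_id},
#'   \code{probe_id}, \code{gene_id}, \code{perfect} (0/1 or logical).
#' @param seed Integer seed controlling duplicate resolution only.
#' @param min_perfect Minimum perfect-probe count for a candidate gene
#'   (default 4, the strict reading of "more than three").
#' @param control_prefix Probe-set id prefix identifying platform control
#'   sets, dropped before mapping (default \code{"AFFX"}).
#' @return Object of class \code{probe_gene_map}: list with
#'   \code{assignments} (named character, probe set -> gene),
#'   \code{removed_multi}, \code{unmapped}, \code{controls} (character
#'   vectors of probe-set ids), and \code{duplicate_resolutions} (data
#'   frame: gene_id, chosen, discarded).
#' @export
map_probe_sets <- function(hits, seed = 1, min_perfect = 4,
                           control_prefix = "AFFX") {
  required <- c("probe_set_id", "probe_id", "gene_id", "perfect")
  missing <- setdiff(required, names(hits))
  if (length(missing))
    stop("hit table lacks columns: ", paste(missing, collapse = ", "))
  if (!nrow(hits)) stop("hit table is empty")
  bad <- which(is.na(hits$probe_set_id) | is.na(hits$gene_id) |
                 is.na(hits$perfect))
  if (length(bad))
    stop(sprintf("malformed hit table row %d: missing field", bad[1]))

  is_control <- startsWith(as.character(hits$probe_set_id), control_prefix)
  controls <- unique(hits$probe_set_id[is_control])
  hits <- hits[!is_control, , drop = FALSE]

  all_sets <- unique(hits$probe_set_id)
  perfect <- hits[as.logical(hits$perfect), , drop = FALSE]
  # perfect probe count per (probe set, gene)
  cnt <- stats::aggregate(probe_id ~ probe_set_id + gene_id, perfect,
                          function(p) length(unique(p)))
  names(cnt)[3] <- "n_perfect"
  cnt <- cnt[cnt$n_perfect >= min_perfect, , drop = FALSE]

  assignments <- character(0)
  removed_multi <- character(0)
  for (ps in all_sets) {
    cand <- cnt[cnt$probe_set_id == ps, , drop = FALSE]
    if (!nrow(cand)) next
    top <- cand$n_perfect == max(cand$n_perfect)
    if (sum(top) > 1) {
      removed_multi <- c(removed_multi, ps)
    } else {
      assignments[ps] <- cand$gene_id[top]
    }
  }
  unmapped <- setdiff(all_sets, c(names(assignments), removed_multi))

  dup <- data.frame(gene_id = character(0), chosen = character(0),
                    discarded = character(0), stringsAsFactors = FALSE)
  if (length(assignments)) {
    set.seed(derive_seed(seed, "probe-dedup"))
    by_gene <- split(names(assignments), assignments)
    for (gene in sort(names(by_gene))) {
      sets <- sort(by_gene[[gene]])
      if (length(sets) > 1) {
        keep <- sets[sample.int(length(sets), 1)]
        drop <- setdiff(sets, keep)
        assignments <- assignments[!names(assignments) %in% drop]
        dup <- rbind(dup, data.frame(gene_id = gene, chosen = keep,
                                     discarded = drop,
                                     stringsAsFactors = FALSE))
      }
    }
  }

  structure(list(assignments = assignments,
                 removed_multi = removed_multi,
                 unmapped = unmapped,
                 controls = controls,
                 duplicate_resolutions = dup),
            class = "probe_gene_map")
}

#' @export
print.probe_gene_map <- function(x, ...) {
  cat("Probe set -> gene map\n")
  cat(sprintf("  assigned:      %d\n", length(x$assignments)))
  cat(sprintf("  multi-mapping: %d (removed)\n", length(x$removed_multi)))
  cat(sprintf("  unmapped:      %d\n", length(x$unmapped)))
  cat(sprintf("  controls:      %d (dropped)\n", length(x$controls)))
  cat(sprintf("  duplicates resolved: %d\n", nrow(x$duplicate_resolutions)))
  invisible(x)
}

#' Write a probe-gene map as a status-annotated TSV
#'
#' @param map A \code{probe_gene_map}.
#' @param path Output path.
#' @export
write_probe_gene_map <- function(map, path) {
  rows <- rbind(
    data.frame(probe_set_id = names(map$assignments),
               gene_id = unname(map$assignments), status = "assigned",
               stringsAsFactors = FALSE),
    data.frame(probe_set_id = map$removed_multi, gene_id = NA,
               status = "removed_multi", stringsAsFactors = FALSE),
    data.frame(probe_set_id = map$unmapped, gene_id = NA,
               status = "unmapped", stringsAsFactors = FALSE),
    data.frame(probe_set_id = map$duplicate_resolutions$discarded,
               gene_id = map$duplicate_resolutions$gene_id,
               status = "duplicate_discarded", stringsAsFactors = FALSE))
  write_tsv(rows[order(rows$probe_set_id), ], path)
}

#' Flag outlier arrays by distribution distance
#'
#' Screens samples whose intensity distribution departs from the pooled
#' distribution of all arrays, in the spirit of boxplot-based array
#' quality metrics. The per-sample statistic is the Kolmogorov-Smirnov
#' distance between the sample's values and the pooled values of all
#' samples; samples beyond the upper boxplot fence (Q3 + k*IQR) of these
#' distances are flagged.
#'
#' @param x Expression matrix (genes x samples).
#' @param k Fence multiplier (default 1.5).
#' @return Character vector of flagged sample ids, in column order.
#' @export
flag_outlier_arrays <- function(x, k = 1.5) {
  if (ncol(x) < 4)
    stop("need at least 4 samples for a meaningful boxplot fence")
  pooled <- as.numeric(x)
  d <- vapply(seq_len(ncol(x)), function(j) {
    suppressWarnings(stats::ks.test(x[, j], pooled)$statistic)
  }, numeric(1))
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fence <- if (iqr == 0) q[2] else q[2] + k * iqr
  colnames(x)[d > fence]
}
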