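#' Local clustering coefficient of one node
#'
#' \eqn{C_i = 2 e_i / (k_i (k_i - 1))}, where \eqn{e_i} is the number of
#' edges among the \eqn{k_i} neighbors of node i; defined as 0 for nodes
#' of degree < 2.
#'
#' @param net A \code{coexp_network}.
#' @param node Node id.
#' @return The clustering coefficient in [0, 1].
#' @export
clustering_coefficient <- function(net, node) {
  if (!node %in% net$nodes) stop("unknown node: ", node)
  e <- net$edges
  nb <- unique(c(e$gene_b[e$gene_a == node], e$gene_a[e$gene_b == node]))
  k <- length(nb)
  if (k < 2) return(0)
  among <- sum(e$gene_a %in% nb & e$gene_b %in% nb)
  2 * among / (k * (k - 1))
}

#' Topology diagnostics of a co-expression network
#'
#' Summarizes the structural signatures that distinguish a biological
#' co-expression network from a random graph: degree distribution and its
#' power-law fit (scale-free check), average clustering coefficient
#' against the Erdos-Renyi expectation (which equals the edge density),
#' and the C(k) curve (mean clustering coefficient of nodes of degree k).
#'
#' @param net A \code{coexp_network}.
#' @param include_low_degree Include degree < 2 nodes (as C = 0) in the
#'   clustering average (default TRUE).
#' @return Object of class \code{topology_report}: list with
#'   \code{n_nodes}, \code{n_edges}, \code{mean_degree}, \code{density},
#'   \code{degree_hist} (k, count), \code{avg_clustering},
#'   \code{ck_curve} (k, mean_c), \code{powerlaw_exponent},
#'   \code{powerlaw_r2}, \code{random_expected_c}.
#' @export
topology_report <- function(net, include_low_degree = TRUE) {
  n <- length(net$nodes)
  m <- nrow(net$edges)
  if (n < 2) stop("degenerate network: fewer than 2 nodes")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  ci[deg < 2] <- 0

  density <- 2 * m / (n * (n - 1))
  hist <- as.data.frame(table(deg), stringsAsFactors = FALSE)
  names(hist) <- c("k", "count")
  hist$k <- as.integer(hist$k)

  avg_c <- if (include_low_degree) mean(ci) else mean(ci[deg >= 2])

  ck <- stats::aggregate(ci, list(k = deg), mean)
  names(ck)[2] <- "mean_c"

  fit_bins <- hist[hist$k > 0 & hist$count > 0, , drop = FALSE]
  if (nrow(fit_bins) >= 2) {
    fit <- stats::lm(log10(count) ~ log10(k), data = fit_bins)
    exponent <- -unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  } else {
    exponent <- NA_real_
    r2 <- NA_real_
  }

  structure(list(n_nodes = n, n_edges = m,
                 mean_degree = 2 * m / n,
                 density = density,
                 degree_hist = hist,
                 avg_clustering = avg_c,
                 ck_curve = ck,
                 powerlaw_exponent = exponent,
                 powerlaw_r2 = r2,
                 random_expected_c = density),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network topology report\n")
  cat(sprintf("  nodes: %d  edges: %d  mean degree: %.1f\n",
              x$n_nodes, x$n_edges, x$mean_degree))
  cat(sprintf("  density: %.4g  avg clustering: %.3f  (random: %.3f)\n",
              x$density, x$avg_clustering, x$random_expected_c))
  cat(sprintf("  power-law fit: exponent %.2f, R^2 %.3f\n",
              x$powerlaw_exponent, x$powerlaw_r2))
  invisible(x)
}

#' Plot topology diagnostics
#'
#' Log-log degree distribution with the fitted power law, and the C(k)
#' curve, side by side.
#'
#' @param x A \code{topology_report}.
#' @param ... Passed to \code{plot}.
#' @export
plot.topology_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$degree_hist[x$degree_hist$k > 0 & x$degree_hist$count > 0, ]
  graphics::plot(h$k, h$count, log = "xy", xlab = "degree k",
                 ylab = "count", main = "Degree distribution", ...)
  if (!is.na(x$powerlaw_exponent))
    graphics::abline(stats::lm(log10(count) ~ log10(k), data = h),
                     col = "grey50", untf = FALSE)
  graphics::plot(x$ck_curve$k, x$ck_curve$mean_c, log = "x",
                 xlab = "degree k", ylab = "C(k)", main = "C(k)", ...)
  graphics::abline(h = x$random_expected_c, lty = 2, col = "grey50")
  invisible(x)
}

#' Write a topology report to TSV files
#'
#' Scalar fields as a key-value table, plus the degree histogram and C(k)
#' curve as separate TSVs.
#'
#' @param rep A \code{topology_report}.
#' @param dir Output directory.
#' @export
write_topology_report <- function(rep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- c("n_nodes", "n_edges", "mean_degree", "density",
               "avg_clustering", "powerlaw_exponent", "powerlaw_r2",
               "random_expected_c")
  write_tsv(data.frame(key = scalars,
                       value = vapply(scalars, function(k)
                         as.numeric(rep[[k]]), numeric(1))),
            file.path(dir, "topology.tsv"))
  write_tsv(rep$degree_hist, file.path(dir, "degree_hist.tsv"))
  write_tsv(rep$ck_curve, file.path(dir, "ck_curve.tsv"))
}
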