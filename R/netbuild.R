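#' Sample redundancy weights
#'
#' Public expression compendia contain near-duplicate arrays (replicate
#' hybridizations, resubmitted series). To stop such redundancy from
#' biasing gene-gene correlations, each sample s receives a weight
#' \deqn{w_s = 1 / \sum_t \max(0, r_{st})^2}
#' where \eqn{r_{st}} is the Pearson correlation between sample columns s
#' and t, the sum running over all samples including s itself (so
#' \eqn{r_{ss} = 1} bounds the weight by 1). A sample with d exact copies
#' gets weight 1/d; a sample with no positively correlated partner keeps
#' weight 1.
#'
#' @param x Expression matrix (genes x samples).
#' @return Named numeric vector of weights in (0, 1], one per sample.
#' @export
sample_weights <- function(x) {
  if (ncol(x) < 3) stop("need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0
  if (any(zero))
    warning("zero-variance sample column(s): ",
            paste(colnames(x)[zero], collapse = ", "),
            "; their correlations are treated as 0 (weight 1)")
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  diag(r)[zero] <- 1                       # r_ss = 1 by convention
  pos <- pmax(r, 0)
  w <- 1 / colSums(pos^2)
  stats::setNames(w, colnames(x))
}

#' Weighted Pearson correlation between two expression profiles
#'
#' \deqn{r = \frac{\sum_s w_s (x_s - \bar x_w)(y_s - \bar y_w)}
#'   {\sqrt{\sum_s w_s (x_s - \bar x_w)^2 \sum_s w_s (y_s - \bar y_w)^2}}}
#' with \eqn{\bar x_w} the weighted mean. With uniform weights this is the
#' ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors over the same samples.
#' @param w Sample weights (from \code{\link{sample_weights}}), recycled if
#'   scalar.
#' @return Correlation in [-1, 1]; \code{NA} with a warning when either
#'   profile has zero weighted variance.
#' @export
weighted_pcc <- function(x, y, w = rep(1, length(x))) {
  if (length(x) != length(y) || length(x) != length(w))
    stop("x, y and w must have equal length")
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) {
    warning("zero weighted variance; correlation undefined")
    return(NA_real_)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Weighted Pearson correlation matrix of all gene pairs
#'
#' Vectorized all-pairs form of \code{\link{weighted_pcc}} over the rows of
#' an expression matrix.
#'
#' @param x Expression matrix (genes x samples).
#' @param w Sample weights.
#' @return Symmetric genes x genes correlation matrix; rows with zero
#'   weighted variance yield \code{NA} entries (with a warning).
#' @export
weighted_cor_matrix <- function(x, w = rep(1, ncol(x))) {
  if (ncol(x) != length(w)) stop("one weight per sample required")
  wn <- w / sum(w)
  m <- as.numeric(x %*% wn)
  xc <- sweep(x, 1, m)
  xw <- sweep(xc, 2, sqrt(w), "*")
  cov <- tcrossprod(xw)
  v <- diag(cov)
  if (any(v == 0))
    warning("gene(s) with zero weighted variance; correlations set to NA")
  v[v == 0] <- NA_real_
  r <- cov / sqrt(outer(v, v))
  # clamp tiny numerical overshoot
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Network density across a grid of correlation cutoffs
#'
#' For each cutoff c, edges are gene pairs with weighted correlation
#' >= c (positive correlations only); the density is 2E/(N(N-1)) over the
#' N genes retaining at least one edge. On compendium-scale data this curve
#' typically falls, reaches an interior minimum, and rises again as high
#' cutoffs leave only densely inter-correlated gene groups.
#'
#' @param x Expression matrix, or a precomputed correlation matrix when
#'   \code{is_cor = TRUE}.
#' @param w Sample weights (ignored when \code{is_cor}).
#' @param cutoffs Strictly increasing grid in (0, 1); default 0.05 to 0.95
#'   by 0.05.
#' @param is_cor Set when \code{x} is already a correlation matrix.
#' @return Data frame with columns \code{cutoff}, \code{n_nodes},
#'   \code{n_edges}, \code{density}.
#' @export
density_scan <- function(x, w = rep(1, ncol(x)),
                         cutoffs = seq(0.05, 0.95, by = 0.05),
                         is_cor = FALSE) {
  if (!length(cutoffs)) stop("cutoff grid is empty")
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly increasing")
  if (any(cutoffs <= 0 | cutoffs >= 1))
    stop("cutoffs must lie in (0, 1)")
  r <- if (is_cor) x else weighted_cor_matrix(x, w)
  diag(r) <- NA
  out <- lapply(cutoffs, function(cc) {
    hit <- !is.na(r) & r >= cc
    deg <- rowSums(hit)
    n <- sum(deg > 0)
    e <- sum(hit) / 2
    data.frame(cutoff = cc, n_nodes = n, n_edges = e,
               density = if (n >= 2) 2 * e / (n * (n - 1)) else 0)
  })
  do.call(rbind, out)
}

#' Choose the network cutoff from a density scan
#'
#' Picks the cutoff at which the density curve attains its minimum and
#' adds a fixed offset, clipped to the top of the grid; ties at the
#' minimum resolve to the smallest such cutoff. On the reference poplar
#' compendium the density minimum sits near PCC 0.65 and the network is
#' built at 0.70, i.e. offset 0.05.
#'
#' @param scan Result of \code{\link{density_scan}}.
#' @param offset Added to the argmin-density cutoff (default 0.05).
#' @return The selected cutoff.
#' @export
select_cutoff <- function(scan, offset = 0.05) {
  if (!nrow(scan)) stop("density scan is empty")
  live <- scan[scan$n_nodes >= 2, , drop = FALSE]   # skip empty networks
  if (!nrow(live)) stop("no cutoff yields a non-degenerate network")
  i <- which(live$density == min(live$density))
  if (length(i) > 1)
    message("density minimum tied at ", length(i),
            " cutoffs; using the smallest")
  min(live$cutoff[i[1]] + offset, max(scan$cutoff))
}

#' Build a co-expression network at a correlation cutoff
#'
#' Nodes are genes, edges are gene pairs whose weighted Pearson
#' correlation meets the cutoff. Genes with no retained edge are excluded,
#' so every node has degree >= 1. By default only positive correlations
#' form edges; set \code{absolute} to threshold on |r|.
#'
#' @param x Expression matrix, or correlation matrix when \code{is_cor}.
#' @param w Sample weights.
#' @param cutoff Correlation cutoff in (0, 1).
#' @param absolute Threshold on absolute correlation instead of signed.
#' @param is_cor Set when \code{x} is already a correlation matrix.
#' @return Object of class \code{coexp_network}: list with \code{nodes}
#'   (character), \code{edges} (data frame gene_a, gene_b, r with
#'   gene_a < gene_b), and \code{cutoff}.
#' @export
build_network <- function(x, w = rep(1, ncol(x)), cutoff,
                          absolute = FALSE, is_cor = FALSE) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  r <- if (is_cor) x else weighted_cor_matrix(x, w)
  ids <- rownames(r)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(nrow(r)))
  val <- if (absolute) abs(r) else r
  val[lower.tri(val, diag = TRUE)] <- NA
  hit <- which(!is.na(val) & val >= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) stop("no edge survives the cutoff: empty network")
  a <- ids[hit[, 1]]
  b <- ids[hit[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(gene_a = a, gene_b = b,
                      r = r[cbind(hit[, 1], hit[, 2])],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  coexp_network(edges, cutoff = cutoff)
}

#' Construct a co-expression network object from an edge list
#'
#' @param edges Data frame with columns \code{gene_a}, \code{gene_b} and
#'   optionally \code{r}; self-edges and duplicate pairs are rejected.
#' @param cutoff The correlation cutoff the edges satisfy (NA if unknown).
#' @return A \code{coexp_network}.
#' @export
coexp_network <- function(edges, cutoff = NA_real_) {
  if (!all(c("gene_a", "gene_b") %in% names(edges)))
    stop("edges need columns gene_a, gene_b")
  if (is.null(edges$r)) edges$r <- NA_real_
  if (any(edges$gene_a == edges$gene_b)) stop("self-edges not allowed")
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b)
  if (anyDuplicated(key)) stop("duplicate edges not allowed")
  edges <- data.frame(gene_a = a, gene_b = b, r = edges$r,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(a, b))), edges = edges,
                 cutoff = cutoff),
            class = "coexp_network")
}

#' @export
print.coexp_network <- function(x, ...) {
  cat(sprintf("Co-expression network: %d nodes, %d edges (cutoff %s)\n",
              length(x$nodes), nrow(x$edges),
              ifelse(is.na(x$cutoff), "?", format(x$cutoff))))
  invisible(x)
}

#' @export
summary.coexp_network <- function(object, ...) {
  deg <- network_degrees(object)
  cat(sprintf("Co-expression network (cutoff %s)\n",
              ifelse(is.na(object$cutoff), "?", format(object$cutoff))))
  cat(sprintf("  nodes: %d   edges: %d\n",
              length(object$nodes), nrow(object$edges)))
  cat(sprintf("  mean degree: %.1f   density: %.4g\n",
              mean(deg), 2 * nrow(object$edges) /
                (length(object$nodes) * (length(object$nodes) - 1))))
  invisible(object)
}

# degree of every node, named
network_degrees <- function(net) {
  tab <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  stats::setNames(as.integer(tab), names(tab))
}

# igraph view of the network (unweighted, undirected)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Write a network edge list as TSV
#'
#' Columns gene_a, gene_b, r (6 decimals), canonically sorted.
#'
#' @param net A \code{coexp_network}.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  e$r <- sprintf("%.6f", e$r)
  write_tsv(e, path)
}
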