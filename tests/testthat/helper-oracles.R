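# Independent brute-force oracles and tiny fixture builders used across
# the suite. These deliberately avoid the package's own computational
# paths: straight loops and direct summations only.

# direct double-sum Newman modularity over all ordered node pairs
oracle_modularity <- function(net, partition) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$gene_a[i], net$edges$gene_b[i]] <- 1
    A[net$edges$gene_b[i], net$edges$gene_a[i]] <- 1
  }
  k <- rowSums(A)
  m2 <- sum(k)
  q <- 0
  for (i in nodes) for (j in nodes) {
    ci <- partition[i]; cj <- partition[j]
    if (!is.na(ci) && !is.na(cj) && ci == cj)
      q <- q + A[i, j] - unname(k[i] * k[j]) / m2
  }
  unname(q / m2)
}

# hypergeometric upper tail by direct summation of point masses
oracle_hyper_tail <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# weighted Pearson correlation by a straight loop over samples
oracle_weighted_pcc <- function(x, y, w) {
  sw <- 0; mx <- 0; my <- 0
  for (i in seq_along(x)) { sw <- sw + w[i]; mx <- mx + w[i] * x[i];
    my <- my + w[i] * y[i] }
  mx <- mx / sw; my <- my / sw
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + w[i] * (x[i] - mx) * (y[i] - my)
    sxx <- sxx + w[i] * (x[i] - mx)^2
    syy <- syy + w[i] * (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# sample redundancy weights by a straight loop
oracle_sample_weights <- function(x) {
  ns <- ncol(x)
  w <- numeric(ns)
  for (s in seq_len(ns)) {
    acc <- 0
    for (t in seq_len(ns)) {
      r <- stats::cor(x[, s], x[, t])
      if (r > 0) acc <- acc + r^2
    }
    w[s] <- 1 / acc
  }
  stats::setNames(w, colnames(x))
}

# per-node clustering coefficient by neighbour-pair enumeration
oracle_clustering <- function(net, node) {
  e <- net$edges
  nb <- unique(c(e$gene_b[e$gene_a == node], e$gene_a[e$gene_b == node]))
  if (length(nb) < 2) return(0)
  pairs <- utils::combn(nb, 2)
  key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  linked <- 0
  for (j in seq_len(ncol(pairs))) {
    a <- min(pairs[, j]); b <- max(pairs[, j])
    if (paste(a, b) %in% key) linked <- linked + 1
  }
  2 * linked / (length(nb) * (length(nb) - 1))
}

# per-window Hamming-distance k-mer count
oracle_count_kmer <- function(seqs, motif, max_mm) {
  k <- nchar(motif)
  mb <- strsplit(motif, "")[[1]]
  total <- 0; with_hit <- 0
  for (s in seqs) {
    sb <- strsplit(s, "")[[1]]
    hits <- 0
    if (length(sb) >= k) {
      for (i in 1:(length(sb) - k + 1)) {
        win <- sb[i:(i + k - 1)]
        if (any(!win %in% c("A", "C", "G", "T"))) next
        if (sum(win != mb) <= max_mm) hits <- hits + 1
      }
    }
    total <- total + hits
    if (hits > 0) with_hit <- with_hit + 1
  }
  c(total, with_hit)
}

# random undirected graph as a coexp_network (n nodes, edge prob p);
# guarantees no isolated node by construction of a spanning path
random_net <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  # spanning path keeps every node at degree >= 1
  path <- cbind(nodes[-n], nodes[-1])
  edges <- unique(rbind(
    data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
               stringsAsFactors = FALSE),
    data.frame(gene_a = path[, 1], gene_b = path[, 2],
               stringsAsFactors = FALSE)))
  coexp_network(edges)
}

# planted-partition graph: two blocks, dense within, sparse between
planted_partition_net <- function(block = 30, p_in = 0.5, p_out = 0.02,
                                  seed = 1) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(2 * block))
  truth <- rep(1:2, each = block)
  names(truth) <- nodes
  edges <- NULL
  for (i in 1:(2 * block - 1)) for (j in (i + 1):(2 * block)) {
    p <- if (truth[i] == truth[j]) p_in else p_out
    if (stats::runif(1) < p)
      edges <- rbind(edges, data.frame(gene_a = nodes[i],
                                       gene_b = nodes[j],
                                       stringsAsFactors = FALSE))
  }
  list(net = coexp_network(edges), truth = truth)
}

# two disjoint triangles
two_triangles <- function() {
  coexp_network(data.frame(
    gene_a = c("a", "a", "b", "d", "d", "e"),
    gene_b = c("b", "c", "c", "e", "f", "f"),
    stringsAsFactors = FALSE))
}

# complete graph on the given node names
clique_net <- function(nodes) {
  pairs <- utils::combn(nodes, 2)
  coexp_network(data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                           stringsAsFactors = FALSE))
}

# small synthetic configuration that runs in seconds; any syn_config
# argument can be overridden through ...
tiny_syn_config <- function(seed = 1, ...) {
  args <- list(
    n_genes = 300, n_samples = 60,
    modules = list(list(size = 30, factor_sd = 1, noise_sd = 0.4),
                   list(size = 30, factor_sd = 1, noise_sd = 0.4)),
    n_redundant_groups = 2, redundancy_size = 3,
    tissues = list(
      list(name = "leaf", n = 30, shift = c(0.8, 0)),
      list(name = "xylem", n = 30, shift = c(0, 0.8))),
    go_terms = data.frame(
      accession = sprintf("GO:%07d", 1:3),
      name = c("secondary cell wall biogenesis", "photosynthesis",
               "cell wall organization"),
      background_rate = c(0.05, 0.10, 0.05),
      planted_module = c(1, NA, 2),
      planted_rate = c(0.8, 0, 0.8)),
    motif = list(consensus = "ACCCCC", planted_module = 1,
                 insertion_rate = 0.8, mutation_prob = 0.05),
    promoter_len = 500, cds_len = 60,
    seed = seed)
  over <- list(...)
  for (nm in names(over)) args[nm] <- list(over[[nm]])  # NULL-safe
  do.call(syn_config, args)
}
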