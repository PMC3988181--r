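#' Newman modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[A_{ij} - \frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j)}
#' over the unweighted adjacency of the network. Nodes absent from the
#' partition (unassigned) contribute nothing. Computed by the equivalent
#' per-community form \eqn{\sum_c [e_c/m - (d_c/2m)^2]} with \eqn{e_c} the
#' intra-community edge count and \eqn{d_c} the total degree of the
#' community's nodes.
#'
#' @param net A \code{coexp_network}.
#' @param partition Named vector mapping node ids to module labels; may
#'   omit nodes (treated as unassigned).
#' @return Modularity Q in [-1, 1].
#' @export
modularity_q <- function(net, partition) {
  m <- nrow(net$edges)
  if (m == 0) stop("modularity undefined for an empty network")
  if (!all(names(partition) %in% net$nodes))
    stop("partition mentions nodes outside the network")
  deg <- network_degrees(net)
  ca <- partition[net$edges$gene_a]
  cb <- partition[net$edges$gene_b]
  intra <- !is.na(ca) & !is.na(cb) & ca == cb
  e_c <- table(factor(ca[intra], levels = unique(partition)))
  d_c <- tapply(deg[names(partition)], partition, sum)
  sum(e_c[names(d_c)] / m) - sum((d_c / (2 * m))^2)
}

# --- internal machinery for spectral module detection -----------------

# leading eigenvector of the generalized modularity matrix of group g
# (dense path); returns NULL when the leading eigenvalue is <= 0
leading_split_vector <- function(Bg) {
  es <- eigen(Bg, symmetric = TRUE)
  if (es$values[1] <= 1e-12) return(NULL)
  es$vectors[, 1]
}

# power iteration fallback for very large components; start vector seeded
leading_split_vector_power <- function(A_g, k_g, two_m, d, n_iter = 1000,
                                       tol = 1e-10) {
  n <- length(k_g)
  alpha <- max(Matrix::rowSums(A_g) + k_g * sum(k_g) / two_m + abs(d))
  x <- stats::rnorm(n)
  x <- x / sqrt(sum(x^2))
  for (it in seq_len(n_iter)) {
    y <- as.numeric(A_g %*% x) - k_g * sum(k_g * x) / two_m - d * x +
      alpha * x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(NULL)
    y <- y / nrm
    if (sum(abs(y - x)) < tol && it > 5) { x <- y; break }
    x <- y
  }
  # shifted eigenvalue back-correction
  lambda <- sum(x * (as.numeric(A_g %*% x) - k_g * sum(k_g * x) / two_m -
                       d * x))
  if (lambda <= 1e-12) return(NULL)
  x
}

# Kernighan-Lin refinement of a +/-1 split vector s against dense Bg.
# Greedy full-sweep with best-prefix rollback, repeated while improving.
kl_refine <- function(Bg, s, max_passes = 10) {
  f <- function(s) sum(s * (Bg %*% s))
  current <- f(s)
  for (pass in seq_len(max_passes)) {
    moved <- rep(FALSE, length(s))
    s_work <- s
    bs <- as.numeric(Bg %*% s_work)
    val <- current
    best_val <- current
    best_state <- s
    for (step in seq_along(s)) {
      gains <- -4 * s_work * bs + 4 * diag(Bg)
      gains[moved] <- -Inf
      i <- which.max(gains)
      val <- val + gains[i]
      bs <- bs - 2 * s_work[i] * Bg[, i]
      s_work[i] <- -s_work[i]
      moved[i] <- TRUE
      if (val > best_val + 1e-12) {
        best_val <- val
        best_state <- s_work
      }
    }
    if (best_val > current + 1e-12) {
      s <- best_state
      current <- best_val
    } else break
  }
  list(s = s, value = current)
}

#' Detect modules by recursive spectral bisection with refinement
#'
#' Partitions the network into modules by maximizing Newman modularity:
#' each connected component is split by the sign pattern of the leading
#' eigenvector of its (generalized) modularity matrix
#' \eqn{B = A - kk^T/2m}, the split is polished by Kernighan-Lin style
#' single-node flips, and splitting recurses while the best split raises Q
#' by at least \code{min_delta_q}. A final global refinement pass moves
#' single nodes between modules to a local Q maximum. Nodes left alone in
#' a module are reported as unassigned (modules have at least 2 members).
#'
#' @param net A \code{coexp_network}.
#' @param min_delta_q Minimum modularity gain for accepting a split.
#' @param seed Seed controlling eigensolver start vectors and tie-breaks.
#' @param dense_limit Components up to this size use a dense eigensolver
#'   and KL refinement; larger ones use power iteration.
#' @return Object of class \code{module_partition}: list with
#'   \code{assignment} (named integer vector, module ids 1..M ordered by
#'   decreasing module size), \code{unassigned} (character vector), and
#'   \code{q} (the modularity of the assignment).
#' @export
detect_modules <- function(net, min_delta_q = 1e-6, seed = 1,
                           dense_limit = 2000) {
  if (!length(net$nodes)) stop("empty network")
  set.seed(derive_seed(seed, "moddetect"))
  nodes <- net$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  ia <- idx[net$edges$gene_a]
  ib <- idx[net$edges$gene_b]
  m <- length(ia)
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = 1,
                            dims = c(n, n))
  deg <- as.numeric(Matrix::rowSums(A))
  two_m <- 2 * m

  # adjacency list for the global refinement
  nbr <- split(c(ib, ia), c(ia, ib))

  groups <- list()
  split_group <- function(g) {
    if (length(g) < 2) { groups[[length(groups) + 1L]] <<- g; return() }
    k_g <- deg[g]
    A_g <- A[g, g, drop = FALSE]
    if (length(g) <= dense_limit) {
      Bg <- as.matrix(A_g) - outer(k_g, k_g) / two_m
      diag(Bg) <- diag(Bg) - rowSums(Bg)
      v <- leading_split_vector(Bg)
      if (is.null(v)) { groups[[length(groups) + 1L]] <<- g; return() }
      s <- ifelse(v >= 0, 1, -1)
      ref <- kl_refine(Bg, s)
      s <- ref$s
      dq <- ref$value / (2 * two_m)
    } else {
      Bg_row <- as.numeric(Matrix::rowSums(A_g)) - k_g * sum(k_g) / two_m
      v <- leading_split_vector_power(A_g, k_g, two_m, Bg_row)
      if (is.null(v)) { groups[[length(groups) + 1L]] <<- g; return() }
      s <- ifelse(v >= 0, 1, -1)
      sBs <- sum(s * (as.numeric(A_g %*% s) - k_g * sum(k_g * s) / two_m -
                        Bg_row * s))
      dq <- sBs / (2 * two_m)
    }
    if (dq < min_delta_q || all(s == s[1])) {
      groups[[length(groups) + 1L]] <<- g
      return()
    }
    split_group(g[s > 0])
    split_group(g[s < 0])
  }

  comp <- igraph::components(as_igraph(net))
  comp_of <- comp$membership[nodes]
  for (cid in seq_len(comp$no)) split_group(unname(which(comp_of == cid)))

  member <- integer(n)
  for (i in seq_along(groups)) member[groups[[i]]] <- i

  member <- refine_partition(member, nbr, deg, m)

  # renumber: singletons -> unassigned; remaining modules get dense ids
  # 1..M by decreasing size (ties broken by original label, deterministic)
  sizes <- table(member)
  single_labels <- as.integer(names(sizes)[sizes == 1])
  unassigned <- nodes[member %in% single_labels]
  keep <- member %in% as.integer(names(sizes)[sizes >= 2])
  labs <- member[keep]
  tab <- table(labs)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  new_id <- stats::setNames(seq_along(ord), names(tab)[ord])
  assignment <- stats::setNames(as.integer(new_id[as.character(labs)]),
                                nodes[keep])
  q <- modularity_q(net, assignment)
  structure(list(assignment = assignment, unassigned = unassigned, q = q),
            class = "module_partition")
}

# greedy single-node moves between neighboring communities until a local
# modularity maximum; member is an integer label vector over node indices
refine_partition <- function(member, nbr, deg, m, max_sweeps = 100) {
  if (m == 0) return(member)
  d_tot <- tapply(deg, member, sum)
  D <- numeric(max(member))
  D[as.integer(names(d_tot))] <- d_tot
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_along(member)) {
      nb <- nbr[[as.character(i)]]
      if (is.null(nb) || !length(nb)) next
      a <- member[i]
      l <- table(member[nb])
      l_ia <- if (as.character(a) %in% names(l)) l[[as.character(a)]] else 0
      cand <- setdiff(as.integer(names(l)), a)
      if (!length(cand)) next
      best_gain <- 1e-12
      best_b <- NA_integer_
      for (b in cand) {
        l_ib <- l[[as.character(b)]]
        gain <- (l_ib - l_ia) / m +
          deg[i] * (D[a] - D[b] - deg[i]) / (2 * m^2)
        if (gain > best_gain) { best_gain <- gain; best_b <- b }
      }
      if (!is.na(best_b)) {
        D[a] <- D[a] - deg[i]
        D[best_b] <- D[best_b] + deg[i]
        member[i] <- best_b
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  member
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("Module partition: %d modules, %d assigned, %d unassigned, Q = %.4f\n",
              length(sizes), length(x$assignment), length(x$unassigned),
              x$q))
  if (length(sizes))
    cat(sprintf("  module sizes: %s%s\n",
                paste(utils::head(sort(as.integer(sizes),
                                       decreasing = TRUE), 10),
                      collapse = ", "),
                if (length(sizes) > 10) ", ..." else ""))
  invisible(x)
}

#' @export
summary.module_partition <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Per-module gene and edge counts
#'
#' @param p A \code{module_partition}.
#' @param net The network the partition was detected on.
#' @return Data frame with columns \code{module}, \code{n_genes},
#'   \code{n_edges} (intra-module edges only), sorted by module id.
#' @export
module_summary <- function(p, net) {
  ids <- sort(unique(p$assignment))
  ca <- p$assignment[net$edges$gene_a]
  cb <- p$assignment[net$edges$gene_b]
  intra <- !is.na(ca) & !is.na(cb) & ca == cb
  e_c <- table(factor(ca[intra], levels = ids))
  n_c <- table(factor(p$assignment, levels = ids))
  data.frame(module = ids,
             n_genes = as.integer(n_c),
             n_edges = as.integer(e_c))
}

#' Write a module partition and per-module edge lists
#'
#' Partition as TSV (gene_id, module_id; unassigned genes get NA), the
#' module summary, and intra-module edges with their correlation values.
#'
#' @param p A \code{module_partition}.
#' @param net The underlying network.
#' @param dir Output directory.
#' @export
write_module_partition <- function(p, net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene_id = c(names(p$assignment), p$unassigned),
                   module_id = c(p$assignment,
                                 rep(NA_integer_, length(p$unassigned))))
  write_tsv(df[order(df$gene_id), ], file.path(dir, "partition.tsv"))
  write_tsv(module_summary(p, net), file.path(dir, "module_summary.tsv"))
  ca <- p$assignment[net$edges$gene_a]
  cb <- p$assignment[net$edges$gene_b]
  intra <- !is.na(ca) & !is.na(cb) & ca == cb
  e <- net$edges[intra, , drop = FALSE]
  e$module_id <- ca[intra]
  e$r <- sprintf("%.6f", e$r)
  write_tsv(e[order(e$module_id, e$gene_a, e$gene_b), ],
            file.path(dir, "module_edges.tsv"))
}
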