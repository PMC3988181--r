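test_that("weighted PCC reduces to ordinary Pearson and honors stated cases", {
  expect_equal(weighted_pcc(c(1, 2, 3), c(2, 4, 6)), 1.0)
  set.seed(5)
  x <- rnorm(12); y <- 2 * x + rnorm(12)
  expect_equal(weighted_pcc(x, -x, runif(12, 0.2, 1)), -1.0)
  expect_equal(weighted_pcc(x, y), cor(x, y), tolerance = 1e-12)
  # hand-weighted case against the straight-loop oracle
  xv <- c(1, 2, 4); yv <- c(1, 3, 2); wv <- c(1, 1, 2)
  expect_equal(weighted_pcc(xv, yv, wv),
               oracle_weighted_pcc(xv, yv, wv), tolerance = 1e-14)
  expect_warning(weighted_pcc(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("redundancy weights follow the positive-correlation-square rule", {
  set.seed(8)
  # d identical copies of one sample, orthogonalized against the rest
  base <- rnorm(400)
  others <- matrix(rnorm(400 * 4), 400, 4)
  others <- apply(others, 2, function(v)
    residuals(lm(v ~ base)))         # kill positive correlation with base
  x <- cbind(base, base, base, others)
  colnames(x) <- paste0("s", 1:7)
  w <- sample_weights(x)
  expect_equal(unname(w[1:3]), rep(1 / 3, 3), tolerance = 0.02)
  # seeded random columns against the brute-force oracle
  y <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("c", 1:5)))
  expect_equal(sample_weights(y), oracle_sample_weights(y),
               tolerance = 1e-12)
})

test_that("weighted correlation matrix matches the pairwise function", {
  set.seed(13)
  x <- matrix(rnorm(8 * 15), 8, 15,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:15)))
  w <- runif(15, 0.3, 1)
  r <- weighted_cor_matrix(x, w)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(r[i, j], weighted_pcc(x[i, ], x[j, ], w),
                 tolerance = 1e-12)
})

test_that("density scan sweeps edges as specified on a uniform-correlation block", {
  r <- matrix(0.9, 10, 10, dimnames = list(paste0("g", 1:10),
                                           paste0("g", 1:10)))
  diag(r) <- 1
  scan <- density_scan(r, cutoffs = c(0.5, 0.85, 0.95), is_cor = TRUE)
  expect_equal(scan$density, c(1, 1, 0))
  one <- density_scan(r, cutoffs = 0.5, is_cor = TRUE)
  expect_identical(nrow(one), 1L)
  expect_error(density_scan(r, cutoffs = numeric(0), is_cor = TRUE),
               "empty")
})

test_that("density is non-monotone with an interior minimum on planted-module data", {
  cfg <- tiny_syn_config(seed = 17)
  x <- simulate_expression(cfg)
  w <- sample_weights(x)
  scan <- density_scan(x, w)
  live <- scan[scan$n_nodes >= 2, ]
  i <- which.min(live$density)
  expect_gt(i, 1)
  expect_lt(i, nrow(live))
})

test_that("cutoff selection adds the offset to the density minimum", {
  scan <- data.frame(cutoff = seq(0.5, 0.9, 0.05),
                     n_nodes = 100, n_edges = 50,
                     density = c(0.5, 0.3, 0.2, 0.12, 0.15, 0.18, 0.3,
                                 0.5, 0.7))
  expect_equal(select_cutoff(scan), 0.70)       # min at 0.65 + 0.05
  expect_equal(select_cutoff(scan, offset = 0), 0.65)
  mono <- data.frame(cutoff = c(0.2, 0.4, 0.6), n_nodes = 10,
                     n_edges = 5, density = c(0.9, 0.5, 0.1))
  expect_equal(select_cutoff(mono), 0.6)        # boundary minimum, clipped
})

test_that("build_network keeps thresholded pairs and excludes isolated genes", {
  r <- diag(3); r[upper.tri(r)] <- 0.99; r[lower.tri(r)] <- 0.99
  dimnames(r) <- list(paste0("g", 1:3), paste0("g", 1:3))
  net <- build_network(r, cutoff = 0.7, is_cor = TRUE)
  expect_identical(length(net$nodes), 3L)
  expect_identical(nrow(net$edges), 3L)
  expect_error(build_network(r, cutoff = 0.999, is_cor = TRUE), "empty")
})

test_that("network construction is invariant to gene and sample permutations", {
  set.seed(23)
  x <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:30)))
  x[1:10, ] <- x[1:10, ] + outer(runif(10, 0.7, 1), rnorm(30, 0, 2))
  w <- sample_weights(x)
  net1 <- build_network(x, w, cutoff = 0.6)
  perm_g <- sample(40); perm_s <- sample(30)
  xp <- x[perm_g, perm_s]
  net2 <- build_network(xp, sample_weights(xp), cutoff = 0.6)
  expect_identical(net1$nodes, net2$nodes)
  expect_equal(net1$edges, net2$edges, tolerance = 1e-12)
})

test_that("redundancy weighting counteracts sample duplication", {
  set.seed(41)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  r_ref <- weighted_cor_matrix(x)                 # unduplicated truth
  dup <- cbind(x, x[, rep(1, 4)])                 # sample 1 copied 4 times
  colnames(dup) <- paste0("d", 1:16)
  r_naive <- weighted_cor_matrix(dup)
  r_weighted <- weighted_cor_matrix(dup, sample_weights(dup))
  err_naive <- max(abs(r_naive - r_ref))
  err_weighted <- max(abs(r_weighted - r_ref))
  expect_lt(err_weighted, err_naive)
})
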