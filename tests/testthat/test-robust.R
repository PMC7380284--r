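# EPRCA, GLS under co-expression covariance, resampling enrichment,
# branch- and degree-preserving nulls.

test_that("partial Spearman matches a brute-force rank computation", {
  D <- c(3.2, 1.5, 4.8, 2.2, 5.9)
  K <- c(2.1, 0.7, 3.9, 3.3, 4.0)
  X <- c(1.0, 2.0, 1.5, 3.5, 0.5)
  # oracle: rank by hand via stats, then the displayed formula
  r_dk <- cor(D, K, method = "spearman")
  r_dx <- cor(D, X, method = "spearman")
  r_kx <- cor(K, X, method = "spearman")
  oracle <- (r_dk - r_dx * r_kx) / sqrt((1 - r_dx^2) * (1 - r_kx^2))
  expect_equal(partial_spearman(D, K, X), oracle, tolerance = 1e-12)

  # D = K with X independent: numerator and denominator cancel to 1
  set.seed(1)
  D <- rnorm(50)
  expect_equal(partial_spearman(D, D, rnorm(50)), 1, tolerance = 1e-12)
  expect_error(partial_spearman(D, rnorm(50), D), "perfectly rank-correlated")
  expect_error(partial_spearman(1:3, 1:3, 3:1), "n >= 4")
})

test_that("partial Spearman of mutually independent vectors is near zero", {
  set.seed(12)
  r <- partial_spearman(rnorm(1e4), rnorm(1e4), rnorm(1e4))
  expect_lt(abs(r), 0.03)
})

test_that("joint-shuffle EPRCA null matches an independent re-implementation", {
  set.seed(31)
  n <- 60L
  X <- rnorm(n); D <- X + rnorm(n); K <- X + rnorm(n)
  Xn <- X + rnorm(n)
  res <- eprca(D, K, Xn, n_perm = 40L, seed = 17L, null = "joint_shuffle")
  set.seed(17L)
  oracle <- vapply(1:40, function(b) {
    idx <- sample.int(n)
    partial_spearman(D[idx], K, Xn[idx])  # same row permutation to D and X'
  }, 0)
  expect_equal(res$null_values, oracle, tolerance = 1e-12)
  # the joint shuffle preserves Spearman(D, X') exactly in every replicate
  set.seed(17L)
  for (b in 1:40) {
    idx <- sample.int(n)
    expect_identical(cor(D[idx], Xn[idx], method = "spearman"),
                     cor(D, Xn, method = "spearman"))
  }
})

test_that("EPRCA under full independence has a uniform-ish p and small theta", {
  ps <- sapply(1:60, function(s) {
    set.seed(900 + s)
    D <- rnorm(150)                      # independent of K and X
    X <- rnorm(150); K <- X + rnorm(150)
    r <- eprca(D, K, X + rnorm(150), n_perm = 120L, seed = s,
               null = "joint_shuffle")
    r$empirical_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(mean(ps < 0.05), 0)  # sanity: the test does sometimes reject
})

test_that("proxy-swap EPRCA null reproduces the spurious correlation level", {
  set.seed(77)
  n <- 400L
  X <- rnorm(n)
  D <- X + rnorm(n); K <- X + rnorm(n); Xn <- X + rnorm(n)  # equal noise
  res <- eprca(D, K, Xn, n_perm = 300L, seed = 5L, null = "proxy_swap")
  # null mean is positive and close to the observed (purely spurious) value
  expect_gt(res$null_mean, 0.15)
  expect_lt(abs(res$null_mean - res$r_obs), 0.1)
  expect_lt(res$theta_adj, 0.15)
  expect_warning(eprca(D, K, Xn, n_perm = 50L, seed = 1L), "unstable")
})

test_that("GLS reproduces the closed-form estimator", {
  # hand example via Delta^-1 = [[4/3, -2/3], [-2/3, 4/3]]
  fit <- gls_fit(G = c(1, 1), dN = c(1, 2),
                 Delta = matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(fit$pi_hat, 0.5, tolerance = 1e-12)

  set.seed(41)
  n <- 30L
  dN <- rexp(n); G <- 2 * dN + rnorm(n)
  # identity covariance reduces to the through-origin OLS slope
  ols <- sum(dN * G) / sum(dN * dN)
  f1 <- gls_fit(G, dN, diag(n))
  expect_equal(f1$pi_hat, ols, tolerance = 1e-10)
  expect_equal(f1$var_pi_hat, f1$sigma2_hat / sum(dN^2), tolerance = 1e-10)

  # exact fit is recovered under any valid covariance
  A <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
  f2 <- gls_fit(3 * dN, dN, A)
  expect_equal(f2$pi_hat, 3, tolerance = 1e-10)

  # factorization solve equals the explicit-inverse formula
  Ainv <- solve(A)
  pi_exp <- drop((t(dN) %*% Ainv %*% G) / (t(dN) %*% Ainv %*% dN))
  expect_equal(gls_fit(G, dN, A)$pi_hat, pi_exp, tolerance = 1e-10)

  expect_error(gls_fit(G, rep(0, n), diag(n)), "identically zero")
  expect_error(gls_fit(c(1, 1), c(1, 2), matrix(c(1, 2, 2, 1), 2)),
               "not positive definite")
})

test_that("resampling enrichment: saturated property gives p = 1, signal is detected", {
  bg <- paste0("g", 1:500)
  prop <- setNames(rep(TRUE, 500), bg)
  r <- resampling_enrichment(bg[1:50], bg, prop, n_draws = 100L, seed = 1L)
  expect_equal(r$empirical_p, 1)
  expect_equal(r$observed, 50)

  # targets enriched 2x for the property
  set.seed(6)
  prop2 <- setNames(runif(500) < 0.2, bg)
  target <- sample(c(bg[prop2], bg), 80L)  # oversample property holders
  r2 <- resampling_enrichment(unique(target), bg, prop2, n_draws = 500L,
                              seed = 2L)
  expect_lt(r2$empirical_p, 0.05)
  expect_error(resampling_enrichment(c("zz"), bg, prop), "subset")
})

test_that("branch-preserving shuffle: singleton groups freeze the permutation", {
  set.seed(13)
  w <- rexp(40L)
  x <- rnorm(40L)
  stat <- function(omega) cor(omega, x, method = "spearman")
  r <- branch_preserving_permutation(w, branch = paste0("b", 1:40), stat,
                                     n_perm = 25L, seed = 3L)
  expect_true(all(r$null_values == r$observed))
  expect_equal(r$empirical_p, 1)
})

test_that("single-branch shuffle equals an unrestricted shuffle draw-for-draw", {
  set.seed(14)
  w <- rexp(100L); x <- rnorm(100L)
  stat <- function(omega) cor(omega, x, method = "spearman")
  r1 <- branch_preserving_permutation(w, rep("b1", 100L), stat,
                                      n_perm = 400L, seed = 9L)
  set.seed(9L)
  r2 <- vapply(1:400, function(b) stat(w[sample.int(100L)]), 0)
  expect_gt(ks.test(r1$null_values, r2)$p.value, 0.01)
})

test_that("degree-strata null concentrates with finer bins", {
  sim <- simulate_dataset(small_sim_config(seed = 23L))
  net <- sim$network
  omega <- setNames(sim$rates$omega, sim$rates$gene)
  stat <- function(network, w) cor(network_degree(network)[names(w)], w,
                                   method = "spearman")
  deg <- network_degree(net)
  fine <- as.character(deg)                       # one stratum per degree
  r_fine <- degree_preserving_null(net, omega, stat, n_perm = 60L, seed = 2L,
                                   mode = "strata", strata_of = fine)
  r_coarse <- degree_preserving_null(net, omega, stat, n_perm = 60L, seed = 2L,
                                     mode = "strata",
                                     strata_of = setNames(rep("all",
                                                              length(deg)),
                                                          names(deg)))
  expect_lt(sd(r_fine$null_values - r_fine$observed),
            sd(r_coarse$null_values - r_coarse$observed))
  # degree-degree statistics are pinned near the observed value in fine strata
  expect_lt(max(abs(r_fine$null_values - r_fine$observed)), 0.05)
})

test_that("rewiring preserves the degree sequence; the triangle is rigid", {
  tri <- gene_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  omega <- setNames(c(0.1, 0.5, 0.9), c("a", "b", "c"))
  stat <- function(network, w) {
    d <- network_degree(network)
    sum(d[network$edges[, 1]] * w[network$edges[, 2]])
  }
  r <- degree_preserving_null(tri, omega, stat, n_perm = 15L, seed = 4L,
                              mode = "rewire")
  # only one simple graph has degree sequence (2, 2, 2) on three nodes
  expect_true(all(r$null_values == r$observed))
  expect_equal(r$empirical_p, 1)

  sim <- simulate_dataset(sim_config(n_genes = 300L, n_tissues = 4L,
                                     samples_per_tissue = 6L, seed = 31L))
  deg0 <- network_degree(sim$network)
  omega2 <- setNames(sim$rates$omega, sim$rates$gene)
  r2 <- degree_preserving_null(sim$network, omega2,
                               function(network, w) {
                                 expect_identical(network_degree(network),
                                                  deg0)
                                 0
                               },
                               n_perm = 5L, seed = 6L, mode = "rewire")
  expect_s3_class(r2, "permutation_result")
})
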