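# Spearman machinery, correlation profiles, tissue clustering,
# highly-variable-gene comparisons, tau downsampling.

test_that("spearman_cor matches the rank formula on hand examples", {
  expect_equal(spearman_cor(1:3, c(2, 4, 6))$rho, 1)
  expect_equal(spearman_cor(1:3, 3:1)$rho, -1)
  # tie-free case: rho = 1 - 6 sum(d^2) / (n (n^2 - 1)), sum(d^2) = 4
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$rho,
               1 - 6 * 4 / (5 * 24))
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "zero variance")
})

test_that("spearman is invariant under monotone transforms of the inputs", {
  set.seed(2)
  x <- rexp(60); y <- x + rnorm(60)
  a <- spearman_cor(x, y)
  b <- spearman_cor(rank(x), rank(y))
  d <- spearman_cor(log(x), y)
  expect_equal(a$rho, b$rho)
  expect_equal(a$rho, d$rho)
})

test_that("correlation profile has one rho per tissue/feature/rate cell", {
  ft <- default_features()
  prof <- correlation_profile(ft, default_sim()$rates)
  expect_equal(dim(prof$rho), c(44L, 9L))
  expect_true(all(prof$rho >= -1 & prof$rho <= 1, na.rm = TRUE))
  expect_true(all(prof$p >= 0 & prof$p <= 1, na.rm = TRUE))
  expect_true(all(c("mean.omega", "variance.dN", "var_to_mean.dS") %in%
                    colnames(prof$rho)))
  # every tissue's mean-omega cell near the configured -0.3
  expect_true(all(abs(prof$rho[, "mean.omega"] + 0.3) < 0.05))
})

test_that("identical per-tissue features give identical profile rows", {
  vals <- rbind(g1 = c(1, 2, 1, 2), g2 = c(5, 7, 5, 7), g3 = c(9, 3, 9, 3),
                g4 = c(2, 8, 2, 8))
  colnames(vals) <- c("a1", "a2", "b1", "b2")
  x <- expression_dataset(vals, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  ft <- build_feature_table(x)
  rates <- evol_rates(paste0("g", 1:4), dN = c(1, 2, 3, 4) / 10,
                      dS = rep(1, 4))
  prof <- correlation_profile(ft, rates)
  expect_equal(prof$rho["A", ], prof$rho["B", ])
})

test_that("tissue clustering merges identical rows first and is deterministic", {
  prof <- list(rho = rbind(T1 = c(0.5, -0.2), T2 = c(0.5, -0.2),
                           T3 = c(-0.4, 0.3)))
  cl <- cluster_tissues(prof)
  expect_equal(cl$hclust$height[1L], 0)
  expect_setequal(cl$order, c("T1", "T2", "T3"))
  first_pair <- rownames(prof$rho)[-cl$hclust$merge[1L, ]]
  expect_setequal(first_pair, c("T1", "T2"))
  expect_equal(cluster_tissues(list(rho = prof$rho[1, , drop = FALSE]))$order,
               "T1")
  prof$rho[1, 1] <- NA
  expect_error(cluster_tissues(prof), "impute_missing")
})

test_that("comparing a tissue's top-variance genes with itself gives p = 1", {
  ft <- default_features()
  res <- compare_top_variable("tissue01", "tissue01", ft,
                              default_sim()$rates, top_n = 500L)
  expect_equal(res$p, 1)
  expect_equal(res$median_a, res$median_b)
  expect_error(compare_top_variable("tissue01", "nope", ft,
                                    default_sim()$rates), "unknown tissue")
  expect_error(compare_top_variable("tissue01", "tissue02", ft,
                                    default_sim()$rates, top_n = 10000L),
               "only")
})

test_that("a tissue whose anchored genes are conserved shows lower omega in its top-variance set", {
  # two tissues with opposite anchor shifts; genes most variable in the
  # shifted-down tissue should evolve slower
  hits <- sapply(1:8, function(s) {
    sim <- simulate_dataset(small_sim_config(anchor_effect_sd = 0.4,
                                             seed = 300L + s))
    ft <- build_feature_table(sim$expression)
    omega <- setNames(sim$rates$omega, sim$rates$gene)
    sh <- sim$truth$anchor_shift
    lo <- names(which.min(sh)); hi <- names(which.max(sh))
    res <- compare_top_variable(lo, hi, ft, sim$rates, top_n = 150L)
    (res$median_a < res$median_b) && res$p < 0.01
  })
  expect_gte(mean(hits), 7 / 8)
})

test_that("tau downsampling: full catalog gives zero sd, flat genes are stable", {
  sim <- simulate_dataset(small_sim_config(seed = 21L))
  ds_full <- tau_downsampling(sim$expression, subset_sizes = 10L,
                              n_reps = 20L, seed = 1L)
  expect_true(all(ds_full$sd_tau == 0, na.rm = TRUE))

  # a nearly flat gene (tau ~ 0) keeps a stable tau under downsampling
  set.seed(77)
  vals <- exp(matrix(rnorm(100 * 240, log(10), 0.2), 100, 240))
  colnames(vals) <- paste0("s", 1:240)
  rownames(vals) <- paste0("g", 1:100)
  tmap <- setNames(rep(paste0("t", 1:12), each = 20), colnames(vals))
  flat_x <- expression_dataset(vals, tmap)
  dsf <- tau_downsampling(flat_x, subset_sizes = 5L, n_reps = 50L, seed = 2L)
  expect_lt(median(dsf$tau_full), 0.1)
  expect_lt(median(dsf$sd_tau[, 1L]), 0.02)
  expect_error(tau_downsampling(sim$expression, subset_sizes = 1L), ">= 2")
  expect_error(tau_downsampling(sim$expression, subset_sizes = 99L),
               "exceeds")
})
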