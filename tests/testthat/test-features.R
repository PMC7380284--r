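# Per-tissue moments, tau, MaxTissue/MaxVariance, residualization.

test_that("per-tissue moments match hand arithmetic", {
  vals <- rbind(gA = c(5, 5), gB = c(1, 3), gC = c(0, 0))
  colnames(vals) <- c("s1", "s2")
  x <- expression_dataset(vals, c(s1 = "T1", s2 = "T1"))
  mom <- per_tissue_moments(x)
  expect_equal(unname(mom$mean[, "T1"]), c(5, 2, 0))
  expect_equal(unname(mom$median[, "T1"]), c(5, 2, 0))
  expect_equal(unname(mom$variance[, "T1"]), c(0, 2, 0))
  # constant gene: ratio 0; (1, 3): ratio 1; all-zero gene: ratio missing
  expect_equal(unname(mom$var_to_mean[, "T1"]), c(0, 1, NA))
})

test_that("variance uses the n - 1 denominator and warns on tiny tissues", {
  vals <- matrix(c(1, 5, 2), 1, 3,
                 dimnames = list("g", c("s1", "s2", "s3")))
  x <- expression_dataset(vals, c(s1 = "A", s2 = "A", s3 = "B"))
  expect_warning(mom <- per_tissue_moments(x), "< 2 samples")
  expect_equal(unname(mom$variance["g", "A"]), var(c(1, 5)))
  expect_true(is.na(mom$variance["g", "B"]))
})

test_that("moments on the log2(x+1) scale", {
  x <- toy_expr()
  mom <- per_tissue_moments(x, scale = "log2p1")
  expect_equal(unname(mom$mean["g2", "A"]), mean(log2(c(1, 3, 2) + 1)))
})

test_that("tau closed forms", {
  expect_equal(compute_tau(c(5, 5, 5)), 0)
  expect_equal(compute_tau(c(8, 0, 0)), 1)
  expect_equal(compute_tau(c(4, 2, 0)), 0.75)  # (0 + 0.5 + 1) / 2
  expect_true(is.na(compute_tau(c(0, 0, 0))))
  expect_error(compute_tau(5), "at least 2")
  expect_error(compute_tau(c(-1, 2)), ">= 0")
})

test_that("tau is scale invariant and monotone under concentration", {
  set.seed(11)
  for (i in 1:25) {
    x <- rexp(sample(3:20, 1))
    expect_equal(compute_tau(x * runif(1, 0.01, 100)), compute_tau(x))
    # moving expression from the weakest tissue onto the strongest never
    # decreases tau
    j <- which.min(x); k <- which.max(x)
    y <- x
    y[k] <- y[k] + x[j]; y[j] <- 0
    expect_gte(compute_tau(y) + 1e-12, compute_tau(x))
  }
})

test_that("tau exclusions drop redundant tissues", {
  x <- c(cortex = 4, cerebellum = 4, liver = 2, lung = 0)
  expect_equal(compute_tau(x, exclude = "cerebellum"),
               compute_tau(c(4, 2, 0)))
})

test_that("MaxTissue argmax with lexicographic tie-break", {
  expect_equal(identify_max_tissue(c(A = 1, B = 2, C = 0.5)),
               list(max_tissue = "B", max_variance = 2))
  expect_equal(identify_max_tissue(c(B = 1, A = 1))$max_tissue, "A")
  expect_equal(identify_max_tissue(c(A = 0.3)),
               list(max_tissue = "A", max_variance = 0.3))
  expect_error(identify_max_tissue(c(A = NA_real_)), "missing")
})

test_that("feature table is internally consistent with the moments", {
  ft <- default_features()
  mom <- attr(ft, "moments")
  expect_equal(ft$max_variance, unname(apply(mom$variance, 1L, max)))
  idx <- cbind(seq_len(nrow(ft)), match(ft$max_tissue, colnames(mom$variance)))
  expect_equal(ft$max_variance, unname(mom$variance[idx]))
  expect_equal(ft$max_level, unname(apply(mom$mean, 1L, max)))
  expect_true(all(ft$tau >= 0 & ft$tau <= 1, na.rm = TRUE))
})

test_that("residualize with k = 0 and no covariates centers each gene", {
  x <- toy_expr()
  r <- residualize(x, k_factors = 0L)
  lv <- log2(x$values + 1)
  for (t in c("A", "B")) {
    sub <- lv[, x$tissue_of == t]
    expect_equal(r$values[, x$tissue_of == t], sub - rowMeans(sub),
                 tolerance = 1e-12)
  }
  expect_error(residualize(x, k_factors = 3L), "must be <")
})

test_that("one latent factor removes an injected batch effect", {
  sim <- simulate_dataset(sim_config(n_genes = 400L, n_tissues = 4L,
                                     samples_per_tissue = 30L,
                                     batch_effect_sd = 0.8, seed = 5L))
  res <- residualize(sim$expression, k_factors = 1L)
  batch <- rep(rep(c(1, -1), length.out = 30L), 4L)  # generator's layout
  cors <- apply(res$values, 1L, function(g) {
    mean(sapply(tissues(res), function(t) {
      idx <- res$tissue_of == t
      abs(cor(g[idx], batch[idx]))
    }))
  })
  expect_gt(mean(cors < 0.05), 0.95)
})

test_that("residualization barely changes feature-rate correlations without confounding", {
  sim <- simulate_dataset(sim_config(n_genes = 800L, n_tissues = 12L,
                                     samples_per_tissue = 30L,
                                     batch_effect_sd = 0, block_rho = 0,
                                     seed = 6L))
  omega <- sim$rates$omega
  rho_pre <- apply(per_tissue_moments(sim$expression,
                                      scale = "log2p1")$variance, 2L,
                   function(v) cor(v, omega, method = "spearman"))
  res <- residualize(sim$expression, k_factors = 1L)
  mom_post <- lapply(tissues(res), function(t) {
    apply(res$values[, res$tissue_of == t, drop = FALSE], 1L, var)
  })
  rho_post <- vapply(mom_post, function(v) cor(v, omega, method = "spearman"),
                     0)
  expect_gt(cor(rho_pre, rho_post, method = "spearman"), 0.99)
})
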