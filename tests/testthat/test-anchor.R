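# Tissue-anchored model: Kruskal-Wallis machinery, gene-count-preserving
# permutation, MaxTissue-delta, signatures, affected-tissue overlap.

test_that("Kruskal-Wallis H matches stats::kruskal.test", {
  # brute-force-checkable case: two groups of three
  g <- rep(c("A", "B"), each = 3L)
  w <- c(1, 2, 3, 4, 5, 6)
  res <- max_tissue_association(g, w)
  kw <- kruskal.test(w, factor(g))
  expect_equal(res$H, unname(kw$statistic), tolerance = 1e-12)
  expect_equal(res$p_analytic, kw$p.value, tolerance = 1e-12)

  set.seed(8)
  for (i in 1:10) {
    g <- sample(letters[1:4], 60L, replace = TRUE)
    w <- round(rexp(60L), 1)  # induces ties; tie correction must agree
    res <- max_tissue_association(g, w)
    kw <- kruskal.test(w, factor(g))
    expect_equal(res$H, unname(kw$statistic), tolerance = 1e-10)
    expect_equal(res$p_analytic, kw$p.value, tolerance = 1e-10)
  }
})

test_that("identical omega everywhere gives H = 0, p = 1 (analytic and permutation)", {
  g <- rep(c("A", "B", "C"), each = 4L)
  w <- rep(0.2, 12L)
  res <- max_tissue_association(g, w)
  expect_equal(res$H, 0)
  expect_equal(res$p_analytic, 1)
  pr <- max_tissue_permutation(g, w, n_perm = 50L, seed = 2L)
  expect_equal(pr$empirical_p, 1)
  expect_error(max_tissue_association(rep("A", 5L), rnorm(5)), "at least 2")
})

test_that("permutation preserves per-tissue gene counts and detects strong anchoring", {
  set.seed(3)
  g <- sample(paste0("t", 1:5), 400L, replace = TRUE)
  shift <- setNames(rnorm(5, sd = 1), paste0("t", 1:5))  # 1-sd tissue shifts
  w <- exp(shift[g] + rnorm(400L, sd = 0.5))
  pr <- max_tissue_permutation(g, w, n_perm = 1000L, seed = 7L)
  expect_equal(pr$empirical_p, 0)
  expect_equal(pr$n_perm, 1000L)
  # analytic and empirical p agree within Monte-Carlo error on a null
  wn <- rexp(400L)
  a <- max_tissue_association(g, wn)
  pn <- max_tissue_permutation(g, wn, n_perm = 1000L, seed = 8L)
  mc <- 2 * sqrt(a$p_analytic * (1 - a$p_analytic) / 1000)
  expect_lt(abs(pn$empirical_p - a$p_analytic), mc + 0.02)
})

test_that("MaxTissue-delta closed forms and affine equivariance", {
  expect_equal(max_tissue_delta(rep(0.3, 10L)), 0)
  w4 <- c(0.1, 0.1, 0.3, 0.3)
  q <- quantile(w4, c(0.25, 0.75), names = FALSE)
  expect_equal(max_tissue_delta(w4), 3.14 * (q[2] - q[1]) / 2)
  set.seed(5)
  w <- rexp(37L)
  a <- runif(1, 0.5, 3); b <- runif(1, -1, 1)
  expect_equal(max_tissue_delta(a * w + b), a * max_tissue_delta(w),
               tolerance = 1e-12)
  expect_error(max_tissue_delta(numeric(0)), "empty")
})

test_that("tissue signature reports medians, delta and counts, sorted", {
  sig <- tissue_signature(c("A", "A", "A", "B"), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(sig$tissue, c("A", "B"))
  expect_equal(sig$median_omega, c(0.2, 0.4))
  expect_equal(sig$n, c(3L, 1L))
})

test_that("leave-one-tissue-out reduces the test to the remaining tissues", {
  g <- rep(c("A", "B", "C"), each = 5L)
  w <- c(rnorm(5, 1), rnorm(5, 2), rnorm(5, 9))
  at <- anchor_test(g, w, n_perm = 50L, seed = 1L, drop_tissue = "C")
  ref <- max_tissue_association(g[1:10], w[1:10])
  expect_equal(at$H, ref$H)
  expect_equal(at$df, 1L)
  expect_false("C" %in% at$signature$tissue)
})

test_that("affected-tissue overlap: perfect dependence and independence", {
  genes <- paste0("g", 1:200)
  mt <- setNames(sample(paste0("t", 1:5), 200L, replace = TRUE), genes)
  ov <- affected_tissue_overlap(mt, mt)
  expect_lt(ov$p, 1e-20)
  expect_true(ov$or_upper_bounded)
  expect_gt(ov$match_odds_ratio, 100)

  set.seed(9)
  at <- setNames(sample(paste0("t", 1:5), 200L, replace = TRUE), genes)
  ov2 <- affected_tissue_overlap(mt, at)
  expect_gt(ov2$p, 1e-4)  # no systematic dependence
  expect_false(ov2$or_upper_bounded)

  expect_error(affected_tissue_overlap(setNames("t1", "g1"),
                                       setNames("t1", "g2")),
               "no shared genes")
  expect_error(affected_tissue_overlap(setNames(rep("t1", 3), genes[1:3]),
                                       setNames(rep("t1", 3), genes[1:3])),
               "degenerate")
})

test_that("genes with out-of-vocabulary MaxTissue are dropped with a message", {
  genes <- paste0("g", 1:60)
  mt <- setNames(rep(c("t1", "t2", "weird"), each = 20L), genes)
  at <- setNames(rep(c("t1", "t2"), 30L), genes)
  expect_message(ov <- affected_tissue_overlap(mt, at), "dropped 20")
  expect_equal(ov$n, 40L)
})

test_that("matched annotation yields enriched odds ratio in simulation", {
  hits <- sapply(1:10, function(s) {
    sim <- simulate_dataset(small_sim_config(seed = 400L + s))
    ft <- build_feature_table(sim$expression)
    ov <- affected_tissue_overlap(setNames(ft$max_tissue, ft$gene),
                                  sim$affected_tissue)
    ov$match_odds_ratio > 1 && ov$p < 0.001
  })
  expect_gte(mean(hits), 0.9)
})
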