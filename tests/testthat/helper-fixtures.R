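# Shared fixtures. The default-scale synthetic dataset is expensive, so it is
# built once per test run and cached, together with its feature table.

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function(seed = 101L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_dataset(sim_config(seed = seed))
  .fixture_env[[key]]
}

default_features <- function(seed = 101L) {
  key <- paste0("ft", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- default_sim(seed)
    .fixture_env[[key]] <- build_feature_table(
      sim$expression, network = sim$network, branch = sim$branch,
      imputation_r2 = sim$imputation_r2)
  }
  .fixture_env[[key]]
}

default_omega <- function(seed = 101L) {
  sim <- default_sim(seed)
  stats::setNames(sim$rates$omega, sim$rates$gene)
}

# A small deterministic expression dataset: 4 genes x 2 tissues x 3 samples.
toy_expr <- function() {
  vals <- rbind(
    g1 = c(5, 5, 5, 5, 5, 5),        # flat everywhere
    g2 = c(1, 3, 2, 8, 10, 12),      # higher and more variable in tissue B
    g3 = c(0, 0, 0, 4, 2, 0),        # tissue-B specific
    g4 = c(2, 4, 6, 2, 4, 6)         # same distribution in both tissues
  )
  colnames(vals) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  expression_dataset(vals, c(a1 = "A", a2 = "A", a3 = "A",
                             b1 = "B", b2 = "B", b3 = "B"))
}

# Small fast simulation used by replicate-heavy tests.
small_sim_config <- function(...) {
  sim_config(n_genes = 2000L, n_tissues = 10L, samples_per_tissue = 25L, ...)
}
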