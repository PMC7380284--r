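# One driver chaining simulate -> features -> correlate -> anchor -> robust
# stats -> boost -> power, with a single configuration and reproducible
# seeds. Stages communicate only through files in the package's plain-text
# formats, so any stage can be run standalone on user data.

.pipeline_stages <- c("simulate", "features", "correlate", "anchor",
                      "eprca", "gls", "boost", "power")

.stage_deps <- list(
  features = "simulate", correlate = "features", anchor = "features",
  eprca = "features", gls = "features", boost = "features",
  power = "simulate"
)

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the selected stages in dependency order, writing every stage
#' output under `out_dir` in the package's TSV/YAML formats together with a
#' manifest (config snapshot, seed, per-stage output paths and checksums)
#' and a plain-text run log. A failed stage halts the run with the manifest
#' reflecting the completed stages.
#'
#' @param config Configuration list, or path to a YAML file. Recognized keys:
#'   `stages` (character vector, default all), `seed` (default 1), `sim`
#'   (overrides for [sim_config()]), `features` (`scale`,
#'   `exclude_tissues`), `anchor` (`n_perm`, `drop_tissue`), `boost`
#'   (`n_trees`, `interaction_depth`, `shrinkage`, `n_splits`), `power`
#'   (`gwas_n`, `alpha`, `phi2`).
#' @param out_dir Output directory (created if needed).
#' @return Object of class `run_manifest`: list with `config`, `seed`,
#'   `outputs` (per stage: named file paths), `checksums`, `log`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("evotiss_run_")) {
  if (is.character(config)) config <- read_config(config)
  stages <- config$stages %||% .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) stop_("unknown stage(s): %s", paste(bad, collapse = ", "))
  for (s in stages) {
    need <- .stage_deps[[s]]
    if (!is.null(need) && !need %in% stages)
      stop_("stage '%s' requires stage '%s'", s, need)
  }
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) writeLines(sprintf(...), log_con)
  logf("evotiss %s | %s", as.character(utils::packageVersion("evotiss")),
       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logf("seed: %d", seed)
  logf("stages: %s", paste(stages, collapse = ", "))
  outputs <- list()
  env <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    logf("-- stage %s", name)
    outputs[[name]] <<- fn()
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    cfg <- do.call(sim_config, c(config$sim %||% list(),
                                 list(seed = seed)))
    logf("sim config: %s",
         paste(sprintf("%s=%s", names(unclass(cfg)),
                       vapply(unclass(cfg), function(v)
                         paste(format(v), collapse = "/"), "")),
               collapse = " "))
    sim <- simulate_dataset(cfg)
    env$sim <- sim
    p <- function(f) file.path(out_dir, f)
    write_expression(sim$expression, p("expression.tsv"), p("tissue_map.tsv"))
    write_rates(sim$rates, p("rates.tsv"))
    write_network(sim$network, p("network.tsv"))
    utils::write.table(
      data.frame(gene = names(sim$branch), branch = unname(sim$branch),
                 affected_tissue = unname(sim$affected_tissue),
                 imputation_r2 = unname(sim$imputation_r2),
                 anchor_tissue = unname(sim$truth$anchor_tissue)),
      p("gene_annotation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    c(expression = p("expression.tsv"), tissue_map = p("tissue_map.tsv"),
      rates = p("rates.tsv"), network = p("network.tsv"),
      annotation = p("gene_annotation.tsv"))
  })

  if ("features" %in% stages) run_stage("features", function() {
    sim <- env$sim
    ft <- build_feature_table(
      sim$expression,
      scale = config$features$scale %||% "raw",
      exclude_tissues = config$features$exclude_tissues,
      network = sim$network, branch = sim$branch,
      imputation_r2 = sim$imputation_r2)
    env$features <- ft
    p <- file.path(out_dir, "feature_table.tsv")
    write_feature_table(ft, p)
    c(feature_table = p)
  })

  if ("correlate" %in% stages) run_stage("correlate", function() {
    prof <- correlation_profile(env$features, env$sim$rates)
    env$profile <- prof
    p <- file.path(out_dir, "correlation_profile.tsv")
    utils::write.table(
      data.frame(tissue = rownames(prof$rho), prof$rho, check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    ord <- cluster_tissues(prof, impute_missing = TRUE)$order
    logf("tissue clustering order: %s", paste(ord, collapse = ", "))
    c(correlation_profile = p)
  })

  if ("anchor" %in% stages) run_stage("anchor", function() {
    ft <- env$features; rates <- env$sim$rates
    omega <- stats::setNames(rates$omega, rates$gene)[ft$gene]
    at <- anchor_test(ft$max_tissue, omega,
                      n_perm = config$anchor$n_perm %||% 1000L,
                      seed = seed,
                      drop_tissue = config$anchor$drop_tissue)
    env$anchor <- at
    logf("anchor test: H = %.2f, analytic p = %.3g, empirical p = %.3g",
         at$H, at$p_analytic, at$perm$empirical_p)
    p <- file.path(out_dir, "tissue_signature.tsv")
    utils::write.table(at$signature, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ov <- affected_tissue_overlap(
      stats::setNames(ft$max_tissue, ft$gene), env$sim$affected_tissue)
    logf("affected-tissue overlap: chi2 = %.2f, p = %.3g, match OR = %.2f",
         ov$chi2, ov$p, ov$match_odds_ratio)
    c(tissue_signature = p)
  })

  if ("eprca" %in% stages) run_stage("eprca", function() {
    # independent effect of expression level on omega given (noisy) breadth
    ft <- env$features; rates <- env$sim$rates
    omega <- stats::setNames(rates$omega, rates$gene)[ft$gene]
    ok <- is.finite(ft$max_level) & is.finite(omega) & is.finite(ft$tau)
    res <- eprca(log2(ft$max_level[ok] + 1), omega[ok], ft$tau[ok],
                 n_perm = config$eprca$n_perm %||% 1000L, seed = seed)
    logf("eprca(level, omega | tau): r = %.3f, p = %.3g, theta = %.3f",
         res$r_obs, res$empirical_p, res$theta_adj)
    p <- file.path(out_dir, "eprca_null.tsv")
    utils::write.table(data.frame(null_value = res$null_values), p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    env$eprca <- res
    c(eprca_null = p)
  })

  if ("gls" %in% stages) run_stage("gls", function() {
    # co-expression-adjusted regression of expression on dN over a block
    rates <- env$sim$rates
    k <- min(500L, nrow(rates))
    idx <- seq_len(k)
    blk <- env$sim$truth$config$coexpr_block_size
    rho <- env$sim$truth$config$block_rho
    Delta <- diag(k)
    for (s in seq(1L, k, by = blk)) {
      e <- min(s + blk - 1L, k)
      Delta[s:e, s:e] <- rho
    }
    diag(Delta) <- 1
    G <- log2(env$features$max_level[idx] + 1)
    fit <- gls_fit(G, rates$dN[idx], Delta)
    logf("gls: pi_hat = %.4f (var %.3g)", fit$pi_hat, fit$var_pi_hat)
    env$gls <- fit
    character(0)
  })

  if ("boost" %in% stages) run_stage("boost", function() {
    ft <- env$features; rates <- env$sim$rates
    omega <- stats::setNames(rates$omega, rates$gene)[ft$gene]
    bc <- config$boost %||% list()
    spec <- importance_spectrum(
      ft, omega,
      n_trees_grid = bc$n_trees_grid %||% c(100L, 500L, 1000L),
      depth_grid = bc$depth_grid %||% c(1L, 4L, 5L),
      shrinkage = bc$shrinkage %||% 0.01, seed = seed)
    env$spectrum <- spec
    cfg <- boost_config(n_trees = bc$n_trees %||% 1000L,
                        interaction_depth = bc$interaction_depth %||% 4L,
                        shrinkage = bc$shrinkage %||% 0.01, seed = seed)
    oos <- out_of_sample_r2(ft, omega, cfg,
                            n_splits = bc$n_splits %||% 20L)
    env$oos <- oos
    logf("boost: top feature %s in %d/%d cells; mean oos adj R2 = %.3f",
         names(which.max(spec$top_rank_freq)),
         max(table(spec$top_feature)), length(spec$top_feature), oos$mean)
    p1 <- file.path(out_dir, "importance_spectrum.tsv")
    utils::write.table(data.frame(feature = rownames(spec$scores),
                                  spec$scores, check.names = FALSE),
                       p1, sep = "\t", quote = FALSE, row.names = FALSE)
    p2 <- file.path(out_dir, "oos_adj_r2.tsv")
    utils::write.table(data.frame(adj_r2 = oos$adj_r2), p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    c(importance_spectrum = p1, oos_adj_r2 = p2)
  })

  if ("power" %in% stages) run_stage("power", function() {
    sim <- env$sim
    pw <- twas_power(sim$imputation_r2,
                     gwas_n = config$power$gwas_n %||% 1000L,
                     alpha = config$power$alpha %||% 0.05,
                     phi2 = config$power$phi2 %||% 0.01,
                     omega = stats::setNames(sim$rates$omega,
                                             sim$rates$gene))
    env$power <- pw
    if (!is.null(pw$groups))
      logf("power: conserved median %.3f vs fast %.3f (p = %.3g)",
           pw$groups$median_conserved, pw$groups$median_fast, pw$groups$p)
    p <- file.path(out_dir, "twas_power.tsv")
    utils::write.table(data.frame(gene = names(sim$imputation_r2),
                                  imputation_r2 = unname(sim$imputation_r2),
                                  power = unname(pw$power)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    c(twas_power = p)
  })

  files <- unlist(outputs, use.names = FALSE)
  manifest <- list(config = config, seed = seed, out_dir = out_dir,
                   outputs = outputs,
                   checksums = if (length(files))
                     as.list(tools::md5sum(files)) else list(),
                   log = log_path,
                   results = as.list(env))
  yaml::write_yaml(list(seed = seed, stages = stages,
                        outputs = lapply(outputs, as.list),
                        checksums = manifest$checksums),
                   file.path(out_dir, "manifest.yaml"))
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %d stage(s) in %s\n", x$seed,
              length(x$outputs), x$out_dir))
  invisible(x)
}
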