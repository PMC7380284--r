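# Joint modeling of evolutionary rate with gradient-boosted regression trees
# and the TWAS statistical-power analysis.

#' Boosted-tree model configuration
#'
#' @param n_trees Number of boosting iterations (the study grid spans 100 to
#'   10000).
#' @param interaction_depth Maximum tree depth (1 = additive stumps; depth d
#'   allows up to d-way interactions).
#' @param shrinkage Learning rate applied to each tree (default 0.01).
#' @param cv_folds Folds for cross-validation (default 10).
#' @param train_fraction Fraction of genes used for training in out-of-sample
#'   evaluation (default 0.7).
#' @param seed Integer seed.
#' @return Validated list of class `boost_config`.
#' @export
boost_config <- function(n_trees = 1000L, interaction_depth = 4L,
                         shrinkage = 0.01, cv_folds = 10L,
                         train_fraction = 0.7, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(is_count(cfg$n_trees), is_count(cfg$interaction_depth),
            is_count(cfg$cv_folds, min = 2L))
  if (cfg$shrinkage <= 0 || cfg$shrinkage > 1)
    stop_("shrinkage must lie in (0, 1]")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop_("train_fraction must lie in (0, 1)")
  structure(cfg, class = "boost_config")
}

# Default model features: the cross-tissue feature set (max expression level,
# MaxVariance, tau, cross-tissue moment summaries) plus degree, branch and
# imputation R2 where available.
.default_boost_features <- c("max_level", "max_variance", "tau",
                             "mean_level", "median_level",
                             "degree", "branch", "imputation_r2")

# Numeric model matrix from a feature table; categorical branch is coded as
# ordered integers (branch1 = oldest). Missing values stay NA (the tree
# learner routes them). All-missing columns are dropped.
.boost_matrix <- function(features, feature_cols = NULL) {
  cols <- feature_cols %||%
    intersect(.default_boost_features, names(features))
  if (!length(cols)) stop_("no usable feature columns")
  m <- sapply(cols, function(cn) {
    v <- features[[cn]]
    if (is.character(v) || is.factor(v))
      as.numeric(factor(v, levels = sort(unique(stats::na.omit(v)))))
    else as.numeric(v)
  })
  m <- matrix(m, nrow = nrow(features), dimnames = list(NULL, cols))
  keep <- colSums(is.finite(m)) > 0L
  if (!any(keep)) stop_("all feature columns are entirely missing")
  m[, keep, drop = FALSE]
}

.xgb_params <- function(config) {
  list(objective = "reg:squarederror", eta = config$shrinkage,
       max_depth = config$interaction_depth, nthread = 1,
       subsample = 1, colsample_bytree = 1)
}

#' Fit a gradient-boosted regression-tree model of evolutionary rate
#'
#' Stagewise additive tree model minimizing squared error, with the
#' configured shrinkage and interaction depth (tree induction is delegated to
#' xgboost with subsampling disabled, so fits are deterministic given the
#' seed). Feature importance is the normalized total squared-error reduction
#' (gain) attributed to each feature, rescaled to sum to 100.
#'
#' @param features A [build_feature_table()] result (or data frame).
#' @param omega Response vector (dN/dS), aligned with the rows of `features`;
#'   genes with missing omega are dropped.
#' @param config A [boost_config()].
#' @param feature_cols Feature columns to use (default: the cross-tissue set
#'   plus degree, branch and imputation R2 where present).
#' @param cv Also compute the `cv_folds`-fold cross-validated R2.
#' @return Object of class `boosted_fit`: list with `model` (xgb.Booster),
#'   `importance` (named, sums to 100), `feature_names`, `n`, `config`, and
#'   `cv_r2` (or `NULL`).
#' @export
fit_boosted <- function(features, omega, config = boost_config(),
                        feature_cols = NULL, cv = FALSE) {
  X <- .boost_matrix(features, feature_cols)
  if (ncol(X) < 2L) stop_("need at least 2 features")
  ok <- is.finite(omega)
  X <- X[ok, , drop = FALSE]; y <- omega[ok]
  if (length(y) < 50L) stop_("need at least 50 genes with omega (got %d)",
                             length(y))
  if (stats::sd(y) == 0) stop_("constant target")
  fit1 <- function(Xtr, ytr) {
    dtrain <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1)
    xgboost::xgb.train(params = c(.xgb_params(config),
                                  base_score = mean(ytr)),
                       data = dtrain, nrounds = config$n_trees,
                       verbose = 0)
  }
  model <- with_seed(config$seed, fit1(X, y))
  imp_tab <- xgboost::xgb.importance(model = model)
  imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (nrow(imp_tab)) imp[imp_tab$Feature] <- imp_tab$Gain * 100
  cv_r2 <- NULL
  if (cv) {
    cv_r2 <- with_seed(config$seed + 1L, {
      fold <- sample(rep_len(seq_len(config$cv_folds), length(y)))
      pred <- numeric(length(y))
      for (f in seq_len(config$cv_folds)) {
        te <- fold == f
        m <- fit1(X[!te, , drop = FALSE], y[!te])
        pred[te] <- stats::predict(m, xgboost::xgb.DMatrix(
          X[te, , drop = FALSE], nthread = 1))
      }
      1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    })
  }
  structure(list(model = model, importance = imp,
                 feature_names = colnames(X), n = length(y),
                 config = config, cv_r2 = cv_r2),
            class = "boosted_fit")
}

#' @export
print.boosted_fit <- function(x, ...) {
  cat(sprintf("<boosted_fit> %d genes, %d trees (depth %d, shrinkage %g)\n",
              x$n, x$config$n_trees, x$config$interaction_depth,
              x$config$shrinkage))
  top <- sort(x$importance, decreasing = TRUE)
  cat("importance:", paste(sprintf("%s %.1f", names(top), top),
                           collapse = ", "), "\n")
  if (!is.null(x$cv_r2)) cat(sprintf("CV R2 = %.3f\n", x$cv_r2))
  invisible(x)
}

#' Feature-importance spectrum over a parameter grid
#'
#' Fits one boosted model per (number of trees, interaction depth) grid cell
#' and assembles the relative importance scores into a spectrum, with a
#' rank-stability summary of how often each feature is top-ranked across
#' cells.
#'
#' @inheritParams fit_boosted
#' @param n_trees_grid,depth_grid Grid values (defaults 100/500/1000 trees,
#'   depths 1/4/5).
#' @param shrinkage,seed Passed to every cell's [boost_config()].
#' @return Object of class `importance_spectrum`: list with `scores` (matrix
#'   features x grid cells, columns summing to 100), `top_feature` (per
#'   cell), `top_rank_freq` (named proportions).
#' @export
importance_spectrum <- function(features, omega,
                                n_trees_grid = c(100L, 500L, 1000L),
                                depth_grid = c(1L, 4L, 5L),
                                shrinkage = 0.01, seed = 1L,
                                feature_cols = NULL) {
  cells <- expand.grid(n_trees = n_trees_grid, depth = depth_grid)
  fits <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- boost_config(n_trees = cells$n_trees[i],
                        interaction_depth = cells$depth[i],
                        shrinkage = shrinkage, seed = seed)
    tryCatch(fit_boosted(features, omega, cfg, feature_cols = feature_cols),
             error = function(e)
               stop_("fit failed at grid cell (n_trees = %d, depth = %d): %s",
                     cells$n_trees[i], cells$depth[i], conditionMessage(e)))
  })
  feats <- fits[[1L]]$feature_names
  scores <- vapply(fits, function(f) f$importance[feats],
                   numeric(length(feats)))
  colnames(scores) <- sprintf("Nt%d_Di%d", cells$n_trees, cells$depth)
  rownames(scores) <- feats
  top <- feats[apply(scores, 2L, which.max)]
  structure(list(scores = scores, top_feature = top,
                 top_rank_freq = table(top) / length(top),
                 grid = cells),
            class = "importance_spectrum")
}

#' Distribution of out-of-sample adjusted R-squared
#'
#' Repeatedly fits the boosted model on a random `train_fraction` of the
#' genes and evaluates the adjusted R-squared on the held-out complement:
#' adjusted R2 = 1 - (1 - R2)(m - 1)/(m - k - 1) with m test genes and k
#' features.
#'
#' @inheritParams fit_boosted
#' @param n_splits Number of random train/test splits (default 100).
#' @return List with `adj_r2` (vector of length `n_splits`), `r2`, `mean`,
#'   and `median` of the adjusted values.
#' @export
out_of_sample_r2 <- function(features, omega, config = boost_config(),
                             n_splits = 100L, feature_cols = NULL) {
  X <- .boost_matrix(features, feature_cols)
  ok <- is.finite(omega)
  X <- X[ok, , drop = FALSE]; y <- omega[ok]
  if (length(y) < 50L) stop_("need at least 50 genes with omega")
  k <- ncol(X)
  m <- length(y) - round(config$train_fraction * length(y))
  if (m - k - 1 <= 0) stop_("test set too small for %d features", k)
  params <- .xgb_params(config)
  res <- with_seed(config$seed, {
    vapply(seq_len(n_splits), function(s) {
      tr <- sample.int(length(y), round(config$train_fraction * length(y)))
      dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                                     nthread = 1)
      mod <- xgboost::xgb.train(params = c(params,
                                           base_score = mean(y[tr])),
                                data = dtrain, nrounds = config$n_trees,
                                verbose = 0)
      yte <- y[-tr]
      pred <- stats::predict(mod, xgboost::xgb.DMatrix(
        X[-tr, , drop = FALSE], nthread = 1))
      r2 <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
      mte <- length(yte)
      c(r2, 1 - (1 - r2) * (mte - 1) / (mte - k - 1))
    }, numeric(2L))
  })
  list(r2 = res[1L, ], adj_r2 = res[2L, ], mean = mean(res[2L, ]),
       median = stats::median(res[2L, ]))
}

#' Statistical power of TWAS gene-trait tests
#'
#' Per-gene power of a transcriptome-wide association test whose association
#' chi-square statistic has noncentrality lambda = N R2 phi2, where N is the
#' GWAS sample size, R2 the gene's expression imputation accuracy, and phi2
#' the fraction of trait variance mediated by the gene's total expression.
#' Power is the upper-tail probability of a noncentral chi-square(1, lambda)
#' beyond the central chi-square(1) critical value at level alpha, so genes
#' with R2 = 0 have power exactly alpha. If omega is supplied, conserved
#' genes (omega < `conserved_max`) are compared with fast-evolving genes
#' (omega > `fast_min`) by a two-sided Mann-Whitney U test on power.
#'
#' @param imputation_r2 Per-gene imputation R-squared in \[0, 1\] (named by
#'   gene if group comparisons are wanted).
#' @param gwas_n GWAS sample size (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param phi2 Trait variance fraction mediated by expression, in (0, 1\]
#'   (default 0.01).
#' @param omega Optional per-gene omega for the conserved / fast-evolving
#'   comparison.
#' @param conserved_max,fast_min Omega thresholds defining the groups
#'   (defaults 0.01 and 1).
#' @param power_target Threshold for the "proportion well-powered" summary
#'   (default 0.8).
#' @return Object of class `power_result`: list with `power` (per gene),
#'   `median_power`, `prop_powered`, and (with omega) `groups`: medians,
#'   proportions, U statistic and p-value of the comparison.
#' @export
twas_power <- function(imputation_r2, gwas_n = 1000L, alpha = 0.05,
                       phi2 = 0.01, omega = NULL, conserved_max = 0.01,
                       fast_min = 1, power_target = 0.8) {
  if (any(imputation_r2 < 0 | imputation_r2 > 1, na.rm = TRUE))
    stop_("imputation_r2 must lie in [0, 1]")
  if (gwas_n < 2) stop_("gwas_n must be >= 2")
  if (phi2 <= 0 || phi2 > 1) stop_("phi2 must lie in (0, 1]")
  crit <- stats::qchisq(1 - alpha, df = 1)
  lambda <- gwas_n * imputation_r2 * phi2
  power <- stats::pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
  out <- list(power = power, lambda = lambda,
              median_power = stats::median(power, na.rm = TRUE),
              prop_powered = mean(power >= power_target, na.rm = TRUE),
              alpha = alpha, gwas_n = gwas_n, phi2 = phi2)
  if (!is.null(omega)) {
    if (!is.null(names(imputation_r2)) && !is.null(names(omega)))
      omega <- omega[names(imputation_r2)]
    cons <- is.finite(omega) & omega < conserved_max
    fast <- is.finite(omega) & omega > fast_min
    if (sum(cons, na.rm = TRUE) >= 2L && sum(fast, na.rm = TRUE) >= 2L) {
      wt <- suppressWarnings(stats::wilcox.test(power[cons], power[fast]))
      out$groups <- list(
        n_conserved = sum(cons), n_fast = sum(fast),
        median_conserved = stats::median(power[cons]),
        median_fast = stats::median(power[fast]),
        prop_powered_conserved = mean(power[cons] >= power_target),
        prop_powered_fast = mean(power[fast] >= power_target),
        U = unname(wt$statistic), p = wt$p.value)
    }
  }
  class(out) <- "power_result"
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> N = %d, alpha = %g, phi2 = %g: median power %.3f\n",
              x$gwas_n, x$alpha, x$phi2, x$median_power))
  if (!is.null(x$groups))
    cat(sprintf("  conserved %.3f vs fast-evolving %.3f (Mann-Whitney p = %.3g)\n",
                x$groups$median_conserved, x$groups$median_fast, x$groups$p))
  invisible(x)
}
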