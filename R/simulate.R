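# Synthetic multi-tissue data generator.
#
# The generator builds the expression structure first - per-gene overall level,
# a tissue-specificity profile (the tau spectrum), gene-specific within-tissue
# noisiness with a lognormal mean-variance relation, and one tissue per gene
# with inflated inter-individual variance - and only then constructs log
# evolutionary rate from *population* summaries of that structure, plus a
# per-tissue median shift for genes anchored in each tissue. Because omega is
# tied to population (not sampled) quantities, realized couplings are the
# population couplings attenuated only by measurement noise, and the share of
# omega variance that is explainable from expression-derived features is set
# by a single configuration knob.

#' Configuration of the synthetic data generator
#'
#' Defaults emulate a reference multi-tissue transcriptome panel: 44 tissues
#' of 70 samples each, a tau spectrum from broadly expressed to tissue
#' specific, a negative coupling of expression level and variance with
#' evolutionary rate in every tissue, per-tissue shifts of median log omega
#' for genes anchored in each tissue, co-expression blocks, a heavy-tailed
#' interaction network, and imputation R-squared positively coupled to omega.
#'
#' @param n_genes,n_tissues,samples_per_tissue Dataset dimensions.
#' @param target_rho_level Target per-tissue Spearman correlation between
#'   per-tissue mean expression and omega, in (-1, 0].
#' @param target_rho_variance Target per-tissue Spearman correlation between
#'   per-tissue expression variance and omega. Realized through the lognormal
#'   mean-variance relation; met exactly when equal to `target_rho_level`
#'   (the default), approximately otherwise.
#' @param anchor_effect_sd Standard deviation of the per-tissue shifts of
#'   median log omega for genes anchored (maximum population expression
#'   variance) in that tissue. 0 disables the tissue-anchored effect.
#' @param tau_mixture Named proportions of `broad`, `intermediate` and
#'   `specific` genes (must sum to 1).
#' @param batch_effect_sd Standard deviation of a rank-one batch factor added
#'   to log expression (0 disables it).
#' @param coexpr_block_size,block_rho Genes are grouped into co-expression
#'   blocks of this size sharing, within each tissue, a per-sample latent
#'   factor that accounts for a fraction `block_rho` of the within-tissue
#'   log-expression variance (marginal variances are preserved).
#' @param degree_exponent Power-law exponent of the network degree
#'   distribution (> 1).
#' @param degree_swap_frac Fraction of genes whose degree assignment is
#'   re-shuffled after rank-matching degree to conservation; 1 decouples
#'   degree from omega, 0 gives the strongest coupling. The marginal degree
#'   law is exact for any value.
#' @param r2_coupling Strength of the positive coupling of imputation
#'   R-squared to omega (0 decouples).
#' @param explainable_variance Fraction of the variance of omega (on the
#'   omega scale) attributable to the population expression features; the
#'   remainder is anchor shifts plus independent noise.
#' @param omega_log_sd Total standard deviation of log omega.
#' @param p_match Probability that a gene's annotated affected tissue equals
#'   its anchor tissue (otherwise uniform over tissues).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L, n_tissues = 44L,
                       samples_per_tissue = 70L,
                       target_rho_level = -0.3, target_rho_variance = -0.3,
                       anchor_effect_sd = 0.3,
                       tau_mixture = c(broad = 0.25, intermediate = 0.5,
                                       specific = 0.25),
                       batch_effect_sd = 0, coexpr_block_size = 50L,
                       block_rho = 0.3, degree_exponent = 2.5,
                       degree_swap_frac = 0.5, r2_coupling = 0.5,
                       explainable_variance = 0.6, omega_log_sd = 0.8,
                       p_match = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(is_count(cfg$n_genes), is_count(cfg$n_tissues, 2L),
            is_count(cfg$samples_per_tissue))
  for (nm in c("target_rho_level", "target_rho_variance"))
    if (cfg[[nm]] > 0 || cfg[[nm]] <= -1)
      stop_("%s must lie in (-1, 0]", nm)
  for (nm in c("anchor_effect_sd", "batch_effect_sd", "r2_coupling"))
    if (cfg[[nm]] < 0) stop_("%s must be >= 0", nm)
  if (abs(sum(tau_mixture) - 1) > 1e-8)
    stop_("tau_mixture proportions must sum to 1")
  if (!setequal(names(tau_mixture), c("broad", "intermediate", "specific")))
    stop_("tau_mixture needs proportions named broad, intermediate, specific")
  if (cfg$coexpr_block_size > cfg$n_genes)
    stop_("coexpr_block_size (%d) exceeds n_genes (%d)",
          cfg$coexpr_block_size, cfg$n_genes)
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop_("block_rho must lie in [0, 1)")
  if (cfg$degree_exponent <= 1) stop_("degree_exponent must be > 1")
  if (cfg$degree_swap_frac < 0 || cfg$degree_swap_frac > 1)
    stop_("degree_swap_frac must lie in [0, 1]")
  if (cfg$explainable_variance < 0 || cfg$explainable_variance >= 1)
    stop_("explainable_variance must lie in [0, 1)")
  if (cfg$omega_log_sd <= 0) stop_("omega_log_sd must be > 0")
  if (cfg$p_match < 0 || cfg$p_match > 1) stop_("p_match must lie in [0, 1]")
  sig_t2 <- cfg$omega_log_sd^2
  sig_s2 <- log1p(cfg$explainable_variance * expm1(sig_t2))
  if (sig_s2 + cfg$anchor_effect_sd^2 > 0.99 * sig_t2)
    stop_(paste0("infeasible config: explainable variance plus anchor",
                 " effect exceed the total log-omega variance"))
  structure(cfg, class = "sim_config")
}

# Internal generator constants (natural-log scale). These define what the
# simulated panel looks like and are not tuning knobs: level spread and
# within-tissue noise are set to give RPKM-like marginals, and the
# tissue-profile gaps give the broad/intermediate/specific tau spectrum.
.sim_const <- list(
  level_meanlog = log(8), level_sdlog = 1.0,   # overall gene abundance
  tissue_base_sd = 0.15,                       # tissue-wide offsets
  profile_jitter = 0.3,                        # per-gene-tissue wobble
  gap_intermediate = 1.5, gap_specific = 3.5,  # preferred-tissue boosts
  sigma_w0 = 0.3, sigma_w_hslope = 0.08,       # within-tissue log-sd and its
  boost_base = 0.55, boost_mslope = 0.7,       # gene-specific variance boost
  sigma_cap = c(0.10, 1.3),                    # bounds on within-tissue sd
  dS_meanlog = log(0.5), dS_sdlog = 0.3,       # neutral-rate distribution
  omega_meanlog = log(0.15),                   # median omega
  rank_atten = 0.97,                           # sampling-noise attenuation
  tau_signal_weight = 0.15,                     # specificity share of signal
  branch_coupling = 0.5,                      # conservation -> gene age
  r2_intercept = -1.5, r2_noise_sd = 1.0       # imputation-R2 logistic
)

#' Simulate a complete synthetic dataset
#'
#' Generates a coherent set of inputs for the full analysis pipeline: an
#' expression dataset, substitution rates, a gene network, branch labels, an
#' affected-tissue annotation, and per-gene imputation R-squared values, all
#' tied together by a latent conservation axis. See [sim_config()] for the
#' generative couplings.
#'
#' @param config A [sim_config()].
#' @return List with elements `expression` ([expression_dataset()]), `rates`
#'   ([evol_rates()]), `network` ([gene_network()]), `branch` (named character
#'   vector), `affected_tissue` (named character vector), `imputation_r2`
#'   (named numeric vector), and `truth` (list of latent quantities: anchor
#'   tissue, per-tissue anchor shifts, population moments, the signal score
#'   and the solved coupling weight) for recovery tests.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cst <- .sim_const
  with_seed(config$seed, {
    G <- config$n_genes; T_ <- config$n_tissues
    S <- config$samples_per_tissue
    genes <- sprintf("g%05d", seq_len(G))
    tis <- sprintf("tissue%02d", seq_len(T_))

    ## --- expression structure (independent of omega) ---------------------
    base_t <- stats::rnorm(T_, 0, cst$tissue_base_sd)
    L <- stats::rnorm(G, cst$level_meanlog, cst$level_sdlog)
    cls <- sample(c("broad", "intermediate", "specific"), G, replace = TRUE,
                  prob = config$tau_mixture[c("broad", "intermediate",
                                              "specific")])
    P <- matrix(stats::rnorm(G * T_, 0, cst$profile_jitter), G, T_)
    n_pref_int <- max(2L, min(6L, T_ - 1L))
    for (i in which(cls == "intermediate")) {
      pref <- sample.int(T_, n_pref_int)
      P[i, pref] <- P[i, pref] + cst$gap_intermediate
    }
    for (i in which(cls == "specific")) {
      pref <- sample.int(T_, 1L)
      P[i, pref] <- P[i, pref] + cst$gap_specific
    }
    mu <- outer(rep(1, G), base_t) + L + P          # population log-means

    h <- stats::rnorm(G)                            # gene noisiness latent
    m <- stats::rnorm(G)                            # variance-boost latent
    sigma_w <- cst$sigma_w0 * exp(cst$sigma_w_hslope * h)
    kappa <- exp(cst$boost_base + cst$boost_mslope * m)
    # inter-individual variability peaks where the gene is most expressed
    B <- max.col(mu, ties.method = "first")
    sigma_gt <- matrix(sigma_w, G, T_)
    sigma_gt[cbind(seq_len(G), B)] <- sigma_w * kappa
    sigma_gt <- pmin(pmax(sigma_gt, cst$sigma_cap[1L]), cst$sigma_cap[2L])

    # population per-tissue moments of the lognormal expression model
    pop_mean_log <- mu + sigma_gt^2 / 2
    pop_var_log <- 2 * mu + sigma_gt^2 + log(expm1(sigma_gt^2))
    anchor <- max.col(pop_var_log, ties.method = "first")
    log_maxvar <- pop_var_log[cbind(seq_len(G), anchor)]

    ## --- evolutionary rate ------------------------------------------------
    sig_t2 <- config$omega_log_sd^2
    sig_s2 <- log1p(config$explainable_variance * expm1(sig_t2))
    sig_e2 <- sig_t2 - sig_s2 - config$anchor_effect_sd^2

    if (sig_s2 > 0 && config$target_rho_level < 0) {
      # signal score: blend of overall level, the mean-adjusted maximum
      # variance (population MaxVariance net of the maximum expression level,
      # i.e. the gene's inter-individual noisiness where it is most variable)
      # and a small tissue-specificity term, weighted so the realized
      # per-tissue level coupling hits its target. Anchor-tissue base offsets
      # are partialled out so that, with anchor_effect_sd = 0, omega carries
      # no tissue-identity signal.
      pm <- exp(pop_mean_log)
      tau_pop <- rowSums(1 - pm / apply(pm, 1L, max)) / (T_ - 1L)
      ns_tau <- norm_score(tau_pop)
      # noisiness where the gene is most variable: the exact lognormal
      # identity log var - 2 log mean = log(e^sigma^2 - 1) at the anchor
      u0 <- log_maxvar - 2 * pop_mean_log[cbind(seq_len(G), anchor)]
      fit <- stats::lm.fit(cbind(1, base_t[anchor]), u0)
      u_var <- norm_score(fit$residuals)
      u <- (u_var - cst$tau_signal_weight * ns_tau) /
        sqrt(1 + cst$tau_signal_weight^2)
      zl <- norm_score(L)
      # the variance coupling rides on the level coupling through the
      # mean-variance relation; aim the solved weight at the midpoint of the
      # predicted level and variance couplings so both land near target
      ns_mu <- cbind(apply(pop_mean_log, 2L, norm_score),
                     apply(pop_var_log, 2L, norm_score))
      c_l <- as.vector(stats::cor(ns_mu, zl))
      c_u <- as.vector(stats::cor(ns_mu, u))
      c_lu <- stats::cor(zl, u)
      rho_pred <- function(w) {
        sdz <- sqrt(w^2 + (1 - w)^2 + 2 * w * (1 - w) * c_lu)
        mean((w * c_l + (1 - w) * c_u) / sdz) *
          sqrt(sig_s2) / config$omega_log_sd * cst$rank_atten
      }
      target <- abs(config$target_rho_level)
      if (rho_pred(1) < target) {
        warn_("target_rho_level %.2f not reachable; using strongest coupling",
              config$target_rho_level)
        w <- 1
      } else if (rho_pred(0) >= target) {
        w <- 0
      } else {
        w <- stats::uniroot(function(w) rho_pred(w) - target, c(0, 1))$root
      }
      z0 <- w * zl + (1 - w) * u
      z <- z0 / sqrt(w^2 + (1 - w)^2 + 2 * w * (1 - w) * c_lu)
    } else {
      z <- norm_score(stats::rnorm(G))
      w <- NA_real_
    }
    delta <- stats::rnorm(T_, 0, config$anchor_effect_sd)
    delta <- delta - mean(delta)
    lw <- cst$omega_meanlog - sqrt(sig_s2) * z + delta[anchor] +
      sqrt(sig_e2) * stats::rnorm(G)
    omega <- exp(lw)
    dS <- exp(stats::rnorm(G, cst$dS_meanlog, cst$dS_sdlog))
    rates <- evol_rates(genes, dN = omega * dS, dS = dS,
                        comparison = "synthetic")

    ## --- expression sampling ---------------------------------------------
    blk <- rep(seq_len(ceiling(G / config$coexpr_block_size)),
               each = config$coexpr_block_size)[seq_len(G)]
    n_blk <- max(blk)
    rho_b <- config$block_rho
    vals <- matrix(0, G, T_ * S)
    tissue_of <- character(T_ * S)
    sample_ids <- character(T_ * S)
    batch_loading <- if (config$batch_effect_sd > 0) stats::rnorm(G) else NULL
    for (t in seq_len(T_)) {
      idx <- (t - 1L) * S + seq_len(S)
      eps <- matrix(stats::rnorm(G * S), G, S)
      if (rho_b > 0) {
        Fb <- matrix(stats::rnorm(n_blk * S), n_blk, S)
        eps <- sqrt(1 - rho_b) * eps + sqrt(rho_b) * Fb[blk, , drop = FALSE]
      }
      lx <- mu[, t] + sigma_gt[, t] * eps
      if (config$batch_effect_sd > 0) {
        b_s <- rep(c(1, -1), length.out = S)
        lx <- lx + config$batch_effect_sd * outer(batch_loading, b_s)
      }
      vals[, idx] <- exp(lx)
      tissue_of[idx] <- tis[t]
      sample_ids[idx] <- sprintf("%s_s%03d", tis[t], seq_len(S))
    }
    dimnames(vals) <- list(genes, sample_ids)
    expr <- expression_dataset(vals, stats::setNames(tissue_of, sample_ids))

    ## --- network, branches, annotations ----------------------------------
    deg <- .rpowerlaw_degree(G, config$degree_exponent, dmax = max(50L, G %/% 10L))
    net <- .rank_matched_network(genes, deg, score = z,
                                 swap_frac = config$degree_swap_frac)
    b_lat <- cst$branch_coupling * z + stats::rnorm(G)
    branch <- stats::setNames(
      paste0("branch", 5L - as.integer(cut(b_lat, stats::quantile(
        b_lat, c(0, 0.25, 0.5, 0.75, 1)), include.lowest = TRUE))), genes)
    affected <- ifelse(stats::runif(G) < config$p_match, anchor,
                       sample.int(T_, G, replace = TRUE))
    affected <- stats::setNames(tis[affected], genes)
    r2 <- stats::plogis(cst$r2_intercept - config$r2_coupling * z +
                          cst$r2_noise_sd * stats::rnorm(G))
    r2 <- pmin(pmax(r2, 0), 1)

    list(expression = expr, rates = rates, network = net,
         branch = branch, affected_tissue = affected,
         imputation_r2 = stats::setNames(r2, genes),
         truth = list(anchor_tissue = stats::setNames(tis[anchor], genes),
                      anchor_shift = stats::setNames(delta, tis),
                      signal = stats::setNames(z, genes),
                      tau_class = stats::setNames(cls, genes),
                      level_weight = w,
                      pop_mean_log = pop_mean_log,
                      pop_var_log = pop_var_log,
                      config = config))
  })
}

# Degrees from a truncated (discrete) power law with exponent `alpha`.
.rpowerlaw_degree <- function(n, alpha, dmin = 1L, dmax = 1000L) {
  u <- stats::runif(n)
  d <- floor(dmin * (1 - u)^(-1 / (alpha - 1)))
  pmin(pmax(d, dmin), dmax)
}

# Assign a degree sequence to genes by rank-matching degree to the
# conservation score, re-shuffling a fraction of positions so the coupling is
# configurable while the marginal degree law stays exact; then realize the
# graph by random stub pairing (self-loops/multi-edges dropped).
.rank_matched_network <- function(genes, deg, score, swap_frac) {
  n <- length(genes)
  ord <- order(score, decreasing = TRUE)     # most conserved first
  deg_sorted <- sort(deg, decreasing = TRUE)
  assigned <- integer(n)
  assigned[ord] <- deg_sorted
  if (swap_frac > 0) {
    k <- round(swap_frac * n)
    if (k >= 2L) {
      pos <- sample.int(n, k)
      assigned[pos] <- assigned[sample(pos)]
    }
  }
  stubs <- rep(seq_len(n), assigned)
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
  stubs <- sample(stubs)
  half <- length(stubs) %/% 2L
  e <- cbind(genes[stubs[seq_len(half)]], genes[stubs[half + seq_len(half)]])
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  suppressMessages(gene_network(e, nodes = genes))
}

#' Add independent noise to a vector
#'
#' Returns X' = X + e with e independent zero-mean Gaussian noise of standard
#' deviation `noise_sd` - the model of a noisy measured version of a latent
#' covariate used by [eprca()].
#'
#' @param x Finite numeric vector.
#' @param noise_sd Nonnegative noise standard deviation (0 returns `x`
#'   unchanged).
#' @param seed Integer seed.
#' @return Numeric vector of the same length.
#' @export
simulate_noisy_proxy <- function(x, noise_sd, seed = NULL) {
  if (!all(is.finite(x))) stop_("x must be finite")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_("noise_sd must be >= 0")
  if (noise_sd == 0) return(x)
  with_seed(seed, x + stats::rnorm(length(x), 0, noise_sd))
}

#' Simulate expression with a known co-expression covariance
#'
#' Draws G = pi_true * dN + eps with eps zero-mean Gaussian and
#' cov(eps) = noise_scale^2 * Delta, the generative model behind the
#' generalized least squares estimator of [gls_fit()].
#'
#' @param n_genes Number of genes (must match `dim(Delta)`).
#' @param Delta Symmetric positive-definite covariance matrix.
#' @param pi_true True effect size.
#' @param dN Vector of nonsynonymous substitution rates.
#' @param noise_scale Residual scale sigma (> 0).
#' @param seed Integer seed.
#' @return Numeric vector G of length `n_genes`.
#' @export
simulate_coexpressed <- function(n_genes, Delta, pi_true, dN,
                                 noise_scale = 1, seed = NULL) {
  stopifnot(length(dN) == n_genes, nrow(Delta) == n_genes,
            ncol(Delta) == n_genes)
  R <- .chol_pd(Delta)
  with_seed(seed, {
    eps <- noise_scale * drop(crossprod(R, stats::rnorm(n_genes)))
    pi_true * dN + eps
  })
}

# Cholesky factor with an informative error naming the failing leading minor.
.chol_pd <- function(Delta) {
  if (!isSymmetric(unname(Delta), tol = 1e-8))
    stop_("Delta must be symmetric")
  R <- tryCatch(chol(Delta), error = function(e) {
    k <- regmatches(conditionMessage(e),
                    regexpr("[0-9]+", conditionMessage(e)))
    stop_("Delta is not positive definite (leading minor %s)",
          if (length(k)) k else "?")
  })
  R
}
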