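## R-side interface to the BayesC-pi Gibbs samplers.

#' MCMC configuration for the BayesC-pi samplers
#'
#' Chain defaults follow common practice for these models: 20,000 cycles,
#' the first 10,000 discarded as burn-in, every 10th remaining sample
#' saved.  Hyperpriors are weakly informative: scaled-inverse-chi-square
#' with nu = 4 for both variances (single trait), inverse-Wishart with
#' v = k + 2 = 4 for the residual and effect covariances (multi-trait);
#' scales are set at initialization from the reference phenotypic
#' variance, assuming half of it is genetic and spread over the expected
#' number of included loci.  pi has a uniform prior and a Beta conjugate
#' update unless fixed.
#'
#' @param n_iter total MCMC cycles
#' @param burn_in cycles discarded
#' @param thin saving interval
#' @param pi_init starting (or fixed) exclusion probability; length 1 (ST)
#'   or 2 (MT)
#' @param pi_fixed keep pi at `pi_init` instead of sampling it
#' @param nu_a,nu_e scaled-inverse-chi-square prior degrees of freedom
#' @param h2_prior assumed heritability used to set the prior scales
#' @param seed integer seed; chains are exactly reproducible per seed
#' @return a `bayes_config` list.
#' @export
bayes_config <- function(n_iter = 20000, burn_in = 10000, thin = 10,
                         pi_init = 0.5, pi_fixed = FALSE,
                         nu_a = 4, nu_e = 4, h2_prior = 0.5, seed = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1, nu_a > 2, nu_e > 2,
            all(pi_init >= 0), all(pi_init <= 1))
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), pi_init = pi_init,
                 pi_fixed = pi_fixed, nu_a = nu_a, nu_e = nu_e,
                 h2_prior = h2_prior, seed = seed),
            class = "bayes_config")
}

## centered genotype matrix for the reference + all individuals
center_dosages <- function(genos) {
  d <- genos$dosages
  if (anyNA(d)) stop("missing dosages; run impute_missing() first")
  sweep(d, 2, colMeans(d))
}

#' Single-trait BayesC-pi
#'
#' Whole-genome regression `y = mu + sum_j m_ij alpha_j + e` where each
#' marker effect is zero with probability pi and `N(0, sigma2_a)` (a
#' variance common to all included markers) otherwise.  Genotypes are
#' centered internally; GEBVs are the centered dosages times the
#' posterior-mean effects, reported for every individual in `genos`.
#'
#' @param genos imputed [genotype_matrix] covering reference and
#'   validation individuals
#' @param y named numeric vector of reference phenotypes (validation
#'   phenotypes withheld by the caller)
#' @param cfg a [bayes_config]
#' @return a `st_bayescpi_fit`: list with `effects` (data.frame: name,
#'   alpha_mean, alpha_sd, incl_freq), `pi_mean`, `mu`, `gebv` (named, all
#'   individuals), `chains` (sigma2_a, sigma2_e, pi) and `n_saved`.
#' @export
st_bayescpi <- function(genos, y, cfg = bayes_config()) {
  ids <- genos$ids
  ref <- match(names(y), ids)
  if (anyNA(ref)) stop("reference id(s) missing from the genotype matrix")
  Mc <- center_dosages(genos)
  Mr <- Mc[ref, , drop = FALSE]
  vy <- var(y)
  sum2pq <- sum(colMeans(Mr^2))
  pi0 <- min(max(cfg$pi_init, 0), 1)
  s_a <- cfg$h2_prior * vy / (max(1 - pi0, 0.01) * max(sum2pq, 1e-8))
  s_e <- (1 - cfg$h2_prior) * vy
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- st_bayescpi_cpp(Mr, as.numeric(y), cfg$n_iter, cfg$burn_in, cfg$thin,
                         pi0, cfg$pi_fixed, cfg$nu_a, s_a, cfg$nu_e, s_e)
  gebv <- as.numeric(Mc %*% res$alpha_mean)
  names(gebv) <- ids
  structure(list(effects = data.frame(name = genos$map$name,
                                      alpha_mean = res$alpha_mean,
                                      alpha_sd = res$alpha_sd,
                                      incl_freq = res$incl_freq),
                 pi_mean = res$pi_mean, mu = res$mu_mean, gebv = gebv,
                 chains = list(sigma2_a = res$s2a_chain,
                               sigma2_e = res$s2e_chain,
                               pi = res$pi_chain),
                 n_saved = res$n_saved, cfg = cfg),
            class = "st_bayescpi_fit")
}

#' @export
print.st_bayescpi_fit <- function(x, ...) {
  cat(sprintf("ST-BayesCpi fit: %d saved samples, posterior mean pi = %.3f\n",
              x$n_saved, x$pi_mean))
  invisible(x)
}

#' Multi-trait (environment-as-trait) BayesC-pi
#'
#' Each locus may affect any combination of the two environment-traits:
#' inclusion is sampled over the four patterns with independent
#' Bernoulli(1 - pi_k) priors, included pairs share the effect covariance
#' where both traits are in, and the residual covariance R has an
#' inverse-Wishart prior.  Every individual is observed for exactly one
#' environment; the unobserved trait value is drawn from its conditional
#' normal in each MCMC iteration.
#'
#' @param genos imputed joint [genotype_matrix] spanning both populations
#' @param y1 named reference phenotypes observed in environment 1
#' @param y2 named reference phenotypes observed in environment 2
#' @param cfg a [bayes_config] (`pi_init` recycled to length 2)
#' @return an `mt_bayescpi_fit`: list with `effects` (per-trait means,
#'   SDs, inclusion frequencies), `pi_mean` (length 2), `mu`, `gebv1`,
#'   `gebv2` (named, all individuals), `Sigma` (posterior-mean effect
#'   covariance), `R` (posterior-mean residual covariance), `rg_chain`
#'   and `rg` (posterior mean of the effect-correlation), `n_saved`.
#' @export
mt_bayescpi <- function(genos, y1, y2, cfg = bayes_config()) {
  ids <- genos$ids
  if (length(intersect(names(y1), names(y2))) > 0)
    stop("an individual cannot be phenotyped in both environments")
  ref <- match(c(names(y1), names(y2)), ids)
  if (anyNA(ref)) stop("reference id(s) missing from the genotype matrix")
  Mc <- center_dosages(genos)
  Mr <- Mc[ref, , drop = FALSE]
  nr <- length(ref)
  obs <- rep(1:2, c(length(y1), length(y2)))
  ymat <- matrix(0, nr, 2)
  ymat[obs == 1, 1] <- y1
  ymat[obs == 2, 2] <- y2
  v1 <- var(y1); v2 <- var(y2)
  sum2pq <- sum(colMeans(Mr^2))
  pi0 <- rep_len(cfg$pi_init, 2)
  sg <- cfg$h2_prior * c(v1, v2) / (pmax(1 - pi0, 0.01) * max(sum2pq, 1e-8))
  S_g <- diag(sg)
  S_e <- diag((1 - cfg$h2_prior) * c(v1, v2))
  v_g <- 4; v_e <- 4
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- mt_bayescpi_cpp(Mr, ymat, as.integer(obs), cfg$n_iter, cfg$burn_in,
                         cfg$thin, pi0, cfg$pi_fixed, v_g, S_g, v_e, S_e)
  gebv1 <- as.numeric(Mc %*% res$alpha_mean[, 1]); names(gebv1) <- ids
  gebv2 <- as.numeric(Mc %*% res$alpha_mean[, 2]); names(gebv2) <- ids
  structure(list(effects = data.frame(name = genos$map$name,
                                      alpha_mean_1 = res$alpha_mean[, 1],
                                      alpha_mean_2 = res$alpha_mean[, 2],
                                      alpha_sd_1 = res$alpha_sd[, 1],
                                      alpha_sd_2 = res$alpha_sd[, 2],
                                      incl_freq_1 = res$incl_freq[, 1],
                                      incl_freq_2 = res$incl_freq[, 2]),
                 pi_mean = res$pi_mean, mu = res$mu_mean,
                 gebv1 = gebv1, gebv2 = gebv2,
                 Sigma = matrix(res$sigma_mean, 2),
                 R = matrix(res$r_mean, 2),
                 rg_chain = res$rg_chain, rg = mean(res$rg_chain),
                 n_jitter = res$n_jitter, n_saved = res$n_saved, cfg = cfg),
            class = "mt_bayescpi_fit")
}

#' @export
print.mt_bayescpi_fit <- function(x, ...) {
  cat(sprintf("MT-BayesCpi fit: %d saved samples, pi = (%.3f, %.3f), effect rg = %.3f\n",
              x$n_saved, x$pi_mean[1], x$pi_mean[2], x$rg))
  invisible(x)
}

#' Mean posterior standard error of marker effects
#'
#' The per-locus posterior SD of the marker effect across saved samples,
#' averaged over loci (per trait for a multi-trait fit).  This is the
#' statistic whose ordering across reference designs (combined > single >
#' multi-trait) diagnoses LD-inconsistency-driven noise in marker-effect
#' estimation.
#'
#' @param fit a `st_bayescpi_fit` or `mt_bayescpi_fit`
#' @param type `"posterior_sd"` (default) or `"mcse"`, the Monte-Carlo
#'   standard error of the posterior-mean effect (posterior SD divided by
#'   the square root of the saved-sample count, treating thinned samples
#'   as approximately independent)
#' @return numeric: mean SE (length 1 for ST, length 2 per trait for MT).
#' @export
marker_effect_se <- function(fit, type = c("posterior_sd", "mcse")) {
  type <- match.arg(type)
  if (fit$n_saved < 100)
    warning("fewer than 100 saved samples; posterior SDs are noisy")
  se <- if (inherits(fit, "st_bayescpi_fit")) mean(fit$effects$alpha_sd)
        else c(mean(fit$effects$alpha_sd_1), mean(fit$effects$alpha_sd_2))
  if (type == "mcse") se / sqrt(fit$n_saved) else se
}
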