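## Genome-side simulation: ancestral haplotype pool, the two-population
## split with Wright-Fisher drift and recombination, and the QTL effect
## model with environment-correlated allele substitution effects.

#' Simulate the ancestral haplotype pool
#'
#' Base haplotypes come from a Gaussian-copula first-order chain: a latent
#' AR(1) process with lag correlation `rho_adjacent` is thresholded at the
#' allele-frequency quantile of each locus, giving adjacent loci a
#' first-order dependence whose strength is monotone in rho.  Allele
#' frequencies vary smoothly along the chromosome (logit-scale AR(1)
#' clamped to the interval 0.08-0.92), so markers survive a MAF >= 0.05 filter with
#' high probability.  The base pool is then drifted as one finite
#' ancestral population for `generations_ancestral` discrete generations:
#' this creates the pair-specific LD pattern (including repulsion-phase
#' pairs) that the two descendant populations inherit in common -- the
#' substrate of a between-population LD consistency below 1 but well
#' above 0.
#'
#' @param cfg a [sim_config]
#' @return a `hap_pool`: list with `haplos` (per-chromosome 0/1 haplotype
#'   matrices; `2 * ne_drift` rows after ancestral drift, `4 * ne_drift`
#'   when `generations_ancestral = 0`), `map` (marker map) and `cfg`.
#' @export
simulate_ancestral_haplotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seeds(cfg)[1])
  m <- cfg$n_snps_per_chrom
  H <- 4L * cfg$ne_drift
  rho <- cfg$rho_adjacent
  haplos <- vector("list", cfg$n_chrom)
  maps <- vector("list", cfg$n_chrom)
  for (ch in seq_len(cfg$n_chrom)) {
    ## allele frequencies vary smoothly along the chromosome (logit-scale
    ## AR(1)); without this, frequency mismatch between neighbours caps
    ## the attainable indicator correlation far below chip-typical LD
    gf <- numeric(m)
    gf[1] <- rnorm(1, 0, 1.1)
    if (m > 1) for (j in 2:m)
      gf[j] <- 0.98 * gf[j - 1] + sqrt(1 - 0.98^2) * rnorm(1, 0, 1.1)
    p <- pmin(pmax(stats::plogis(gf), 0.08), 0.92)
    z <- matrix(0, H, m)
    z[, 1] <- rnorm(H)
    if (m > 1) {
      eps <- matrix(rnorm(H * (m - 1)), H, m - 1)
      sc <- sqrt(1 - rho^2)
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sc * eps[, j - 1]
    }
    hap <- matrix(0L, H, m)
    hap[z < rep(qnorm(p), each = H)] <- 1L
    haplos[[ch]] <- hap
    gaps <- round(runif(m, 0.5 * cfg$mean_adjacent_bp, 1.5 * cfg$mean_adjacent_bp))
    maps[[ch]] <- data.frame(chr = ch, pos = cumsum(gaps),
                             name = sprintf("snp%d_%d", ch, seq_len(m)))
  }
  ## drift the base pool as one ancestral population so that both
  ## descendant populations share a single realized LD pattern
  if (cfg$generations_ancestral > 0) {
    ne <- cfg$ne_drift
    frac_list <- lapply(haplos, function(h) seq_len(ncol(h)) / ncol(h))
    rows <- sample.int(H, 2L * ne, replace = TRUE)
    haps <- lapply(haplos, function(h) h[rows, , drop = FALSE])
    sex <- draw_sexes(ne)
    for (g in seq_len(cfg$generations_ancestral)) {
      sires <- sample(which(sex == 1), ne, replace = TRUE)
      dams <- sample(which(sex == 0), ne, replace = TRUE)
      haps <- breed_generation(haps, sires, dams, frac_list,
                               cfg$morgans_per_chrom)
      sex <- draw_sexes(ne)
    }
    haplos <- haps
  }
  structure(list(haplos = haplos, map = do.call(rbind, maps), cfg = cfg),
            class = "hap_pool")
}

#' @export
print.hap_pool <- function(x, ...) {
  cat("ancestral haplotype pool:", nrow(x$haplos[[1]]), "haplotypes x",
      nrow(x$map), "markers on", length(x$haplos), "chromosomes\n")
  invisible(x)
}

## one meiosis for one chromosome: crossover count ~ Poisson(morgans),
## uniform breakpoints on the genetic map (proportional to marker index)
make_gamete <- function(hap_a, hap_b, frac, morgans) {
  k <- rpois(1L, morgans)
  start <- runif(1) < 0.5
  if (k == 0L) return(if (start) hap_a else hap_b)
  br <- sort(runif(k))
  parity <- (findInterval(frac, br) + !start) %% 2L
  ifelse(parity == 0L, hap_a, hap_b)
}

## breed one generation: parents' per-chromosome haplotype matrices
## (2 rows per individual), sire/dam indices per offspring
breed_generation <- function(par_haps, sires, dams, frac_list, morgans) {
  n_off <- length(sires)
  lapply(seq_along(par_haps), function(ch) {
    ph <- par_haps[[ch]]
    out <- matrix(0L, 2L * n_off, ncol(ph))
    for (i in seq_len(n_off)) {
      s <- sires[i]; d <- dams[i]
      out[2L * i - 1L, ] <- make_gamete(ph[2L * s - 1L, ], ph[2L * s, ],
                                        frac_list[[ch]], morgans)
      out[2L * i, ] <- make_gamete(ph[2L * d - 1L, ], ph[2L * d, ],
                                   frac_list[[ch]], morgans)
    }
    out
  })
}

draw_sexes <- function(n) {
  sex <- rbinom(n, 1, 0.5)           # 1 = male
  if (all(sex == 1)) sex[1] <- 0
  if (all(sex == 0)) sex[1] <- 1
  sex
}

## drift one population for `gens` generations from pooled founders, then
## expand to n_final recorded offspring.  Keeps haplotypes for the last
## three recorded generations (grandparents, parents, final).
drift_population <- function(pool, cfg, n_final, pop_name) {
  ne <- cfg$ne_drift
  frac_list <- lapply(pool$haplos, function(h) seq_len(ncol(h)) / ncol(h))
  founder_rows <- sample.int(nrow(pool$haplos[[1]]), 2L * ne, replace = TRUE)
  haps <- lapply(pool$haplos, function(h) h[founder_rows, , drop = FALSE])
  sex <- draw_sexes(ne)
  gens <- cfg$generations_split
  prev <- NULL; prev_sex <- NULL; prev_par <- NULL
  for (g in seq_len(gens)) {
    males <- which(sex == 1); females <- which(sex == 0)
    sires <- sample(males, ne, replace = TRUE)
    dams <- sample(females, ne, replace = TRUE)
    prev <- haps; prev_sex <- sex; prev_par <- cbind(sires, dams)
    haps <- breed_generation(haps, sires, dams, frac_list, cfg$morgans_per_chrom)
    sex <- draw_sexes(ne)
  }
  ## final recorded generation
  males <- which(sex == 1); females <- which(sex == 0)
  f_sires <- sample(males, n_final, replace = TRUE)
  f_dams <- sample(females, n_final, replace = TRUE)
  fin <- breed_generation(haps, f_sires, f_dams, frac_list, cfg$morgans_per_chrom)
  f_sex <- draw_sexes(n_final)

  id_of <- function(gen, i) sprintf("%s_g%d_%04d", pop_name, gen, i)
  have_gp <- gens >= 1 && !is.null(prev)
  ped <- list()
  if (have_gp) {
    ped$gp <- data.frame(id = id_of(gens - 1L, seq_len(ne)),
                         sire = "0", dam = "0",
                         sex = prev_sex, generation = gens - 1L)
    ped$par <- data.frame(id = id_of(gens, seq_len(ne)),
                          sire = id_of(gens - 1L, prev_par[, 1]),
                          dam = id_of(gens - 1L, prev_par[, 2]),
                          sex = sex, generation = gens)
  } else {
    ped$par <- data.frame(id = id_of(gens, seq_len(ne)),
                          sire = "0", dam = "0",
                          sex = sex, generation = gens)
  }
  ped$fin <- data.frame(id = id_of(gens + 1L, seq_len(n_final)),
                        sire = id_of(gens, f_sires),
                        dam = id_of(gens, f_dams),
                        sex = f_sex, generation = gens + 1L)
  pedigree <- do.call(rbind, ped)
  pedigree$pop <- pop_name
  rownames(pedigree) <- NULL

  cat_haps <- function(hl) do.call(cbind, hl)
  hap_all <- rbind(if (have_gp) cat_haps(prev),
                   cat_haps(haps), cat_haps(fin))
  hap_ids <- c(if (have_gp) ped$gp$id, ped$par$id, ped$fin$id)

  list(pedigree = pedigree, hap_all = hap_all, hap_ids = hap_ids,
       final_ids = ped$fin$id, hap_final = cat_haps(fin))
}

#' Split the ancestral pool into two drifted populations
#'
#' Both populations are founded independently from the common pool and
#' random-mate for `generations_split` discrete generations with one
#' crossover per Morgan, so their adjacent-pair LD patterns decorrelate by
#' drift while each keeps the ancestral LD strength.  The last three
#' generations of each population are recorded in its pedigree (earlier
#' ancestors are treated as unknown founders); only the final generation
#' is genotyped, with calls masked at `missing_geno_rate`.  No individual
#' appears in both pedigrees.
#'
#' @param pool a [simulate_ancestral_haplotypes] result
#' @param cfg the same [sim_config]
#' @return list with `geno1`, `geno2` ([genotype_matrix] per population,
#'   final generation, missing calls masked), `ped1`, `ped2` (pedigree
#'   data.frames: id, sire, dam, sex, generation, pop; "0" = unknown),
#'   `hap1`, `hap2` (phased 0/1 haplotypes of the genotyped individuals,
#'   two rows per individual) and `hap_ped1`, `hap_ped2` (haplotypes of
#'   all pedigree-recorded individuals, for breeding-value truth).
#' @export
split_and_drift <- function(pool, cfg) {
  if (2L * cfg$ne_drift > nrow(pool$haplos[[1]]) * 2L)
    stop("haplotype pool too small for the requested population size")
  set.seed(sim_seeds(cfg)[2])
  p1 <- drift_population(pool, cfg, cfg$n_pop1, "pop1")
  p2 <- drift_population(pool, cfg, cfg$n_pop2, "pop2")
  mask <- function(d) {
    if (cfg$missing_geno_rate > 0) {
      hit <- matrix(runif(length(d)) < cfg$missing_geno_rate, nrow(d))
      d[hit] <- NA_integer_
    }
    d
  }
  dos <- function(h) {
    n <- nrow(h) / 2L
    h[2L * seq_len(n) - 1L, , drop = FALSE] + h[2L * seq_len(n), , drop = FALSE]
  }
  d1 <- dos(p1$hap_final); rownames(d1) <- p1$final_ids
  d2 <- dos(p2$hap_final); rownames(d2) <- p2$final_ids
  geno1 <- genotype_matrix(mask(d1), pool$map, pop = "pop1")
  geno2 <- genotype_matrix(mask(d2), pool$map, pop = "pop2")
  list(geno1 = geno1, geno2 = geno2,
       ped1 = p1$pedigree, ped2 = p2$pedigree,
       hap1 = p1$hap_final, hap2 = p2$hap_final,
       hap_ped1 = p1$hap_all, hap_ped_ids1 = p1$hap_ids,
       hap_ped2 = p2$hap_all, hap_ped_ids2 = p2$hap_ids,
       map = pool$map)
}

#' Draw environment-correlated QTL effects
#'
#' Causal loci are sampled among the genotyped markers; every QTL is
#' pleiotropic across the two environments, with allele substitution
#' effects drawn from a bivariate normal with correlation `rg_env` per
#' trait.  The G x E interaction of the simulated world is therefore
#' expressed purely as a between-environment genetic correlation below 1.
#'
#' @param cfg a [sim_config]
#' @param n_markers total marker count the indices refer to
#' @return list with `qtl_indices` and `effects` (named list per trait of
#'   n_qtl x 2 matrices, columns = environments).
#' @export
simulate_qtl_effects <- function(cfg, n_markers = cfg$n_chrom * cfg$n_snps_per_chrom) {
  set.seed(sim_seeds(cfg)[3])
  qtl <- sort(sample.int(n_markers, cfg$n_qtl))
  effects <- lapply(seq_len(nrow(cfg$traits)), function(t) {
    rg <- cfg$traits$rg_env[t]
    z1 <- rnorm(cfg$n_qtl)
    z2 <- rg * z1 + sqrt(1 - rg^2) * rnorm(cfg$n_qtl)
    cbind(env1 = z1, env2 = z2)
  })
  names(effects) <- cfg$traits$trait
  list(qtl_indices = qtl, effects = effects)
}
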