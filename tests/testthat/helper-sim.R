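# Shared fixture builders.  Expensive simulated datasets are memoized in
# an environment so multiple test files can reuse them within one run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## one growth trait, moderate sizes, drifted LD -- the workhorse dataset
small_gxe_sim <- function() {
  fixture("small_gxe_sim", function() {
    tr <- data.frame(trait = "GT", type = "growth", h2_pop1 = 0.35,
                     h2_pop2 = 0.40, repeatability = NA, rg_env = 0.6)
    simulate_gxe(sim_config(
      n_pop1 = 300, n_pop2 = 150, n_chrom = 3, n_snps_per_chrom = 80,
      n_qtl = 60, ne_drift = 50, generations_split = 8, traits = tr,
      seed = 101))
  })
}

## the headline cross-validation world: rg_env = 0.6, 800 + 400 genotyped,
## 2000 delivered markers with the causal loci masked from the panel (the
## emulated chip tags QTL through LD only), drifted LD consistency ~ 0.55.
## Corrected phenotypes come from the full pedigree-REML pipeline.
headline_cv_world <- function() {
  fixture("headline_cv_world", function() {
    tr <- data.frame(trait = "GT", type = "growth", h2_pop1 = 0.35,
                     h2_pop2 = 0.40, repeatability = NA, rg_env = 0.6)
    cfg <- sim_config(n_pop1 = 800, n_pop2 = 400, n_chrom = 5,
                      n_snps_per_chrom = 440, n_qtl = 200, traits = tr,
                      seed = 202, mask_qtl = TRUE)
    sim <- simulate_gxe(cfg)
    ycp <- yc_pipeline(sim, "GT")
    geno <- impute_missing(merge_genotypes(sim$geno1, sim$geno2),
                           "mean_dosage")
    list(sim = sim, yc = ycp$yc, vc = ycp$vc, geno = geno)
  })
}

## iid binomial genotype matrix with a named-id dosage matrix
random_genotypes <- function(n, m, seed = 1, pop = "pop1") {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(d) <- sprintf("i%03d", seq_len(n))
  genotype_matrix(d, data.frame(chr = 1, pos = seq_len(m) * 1000,
                                name = paste0("s", seq_len(m))), pop = pop)
}

## additive phenotypes from a random sparse architecture
random_trait <- function(genos, n_qtl = 20, h2 = 0.5, seed = 2) {
  set.seed(seed)
  d <- genos$dosages
  qtl <- sample(ncol(d), n_qtl)
  tbv <- as.numeric(scale(d[, qtl, drop = FALSE] %*% rnorm(n_qtl),
                          scale = FALSE))
  e_sd <- sqrt(var(tbv) * (1 - h2) / h2)
  y <- setNames(5 + tbv + rnorm(nrow(d), 0, e_sd), genos$ids)
  list(y = y, tbv = setNames(tbv, genos$ids), qtl = qtl)
}

## random valid pedigree: founders first, then offspring of earlier animals
random_pedigree <- function(n, n_founders = max(4, n %/% 5), seed = 1) {
  set.seed(seed)
  id <- sprintf("p%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1):n) {
    pair <- sample(id[seq_len(i - 1)], 2)
    sire[i] <- pair[1]; dam[i] <- pair[2]
  }
  data.frame(id = id, sire = sire, dam = dam)
}
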