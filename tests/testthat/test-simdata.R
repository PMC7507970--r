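test_that("simulation is fully determined by the seed", {
  cfg <- sim_config(n_pop1 = 40, n_pop2 = 30, n_chrom = 2, n_snps_per_chrom = 30,
                    n_qtl = 10, ne_drift = 20, generations_split = 3, seed = 7)
  pool1 <- simulate_ancestral_haplotypes(cfg)
  pool2 <- simulate_ancestral_haplotypes(cfg)
  expect_identical(pool1$haplos, pool2$haplos)
  s1 <- simulate_gxe(cfg)
  s2 <- simulate_gxe(cfg)
  expect_identical(s1$geno1$dosages, s2$geno1$dosages)
  expect_identical(s1$pheno, s2$pheno)
  s3 <- simulate_gxe(sim_config(n_pop1 = 40, n_pop2 = 30, n_chrom = 2,
                                n_snps_per_chrom = 30, n_qtl = 10,
                                ne_drift = 20, generations_split = 3, seed = 8))
  expect_false(identical(s1$geno1$dosages, s3$geno1$dosages))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(rho_adjacent = 1), "rho_adjacent")
  expect_error(sim_config(rho_adjacent = -0.1), "rho_adjacent")
  expect_error(sim_config(n_qtl = 1e7), "n_qtl")
  tr <- default_traits()
  tr$repeatability[3] <- 0.01          # below the trait's h2
  expect_error(sim_config(traits = tr), "repeatability")
  tr <- default_traits(); tr$rg_env[1] <- 1.5
  expect_error(sim_config(traits = tr), "rg_env")
})

test_that("adjacent LD is monotone in the ancestral copula correlation", {
  mean_r2 <- sapply(c(0, 0.5, 0.9), function(rho) {
    cfg <- sim_config(n_pop1 = 150, n_pop2 = 10, n_chrom = 2,
                      n_snps_per_chrom = 120, n_qtl = 10, ne_drift = 80,
                      generations_split = 0, generations_ancestral = 0,
                      rho_adjacent = rho, seed = 11,
                      missing_geno_rate = 0)
    pool <- simulate_ancestral_haplotypes(cfg)
    drift <- split_and_drift(pool, cfg)
    adjacent_ld(drift$geno1, drift$hap1)$summary$mean_r2
  })
  ## rho = 0: near the independence baseline; strictly increasing in rho
  expect_lt(mean_r2[1], 0.05)
  expect_gt(mean_r2[2], mean_r2[1])
  expect_gt(mean_r2[3], mean_r2[2])
  expect_gt(mean_r2[3], 0.2)
})

test_that("LD consistency decays with drift generations", {
  cons <- sapply(c(0, 30), function(gens) {
    cfg <- sim_config(n_pop1 = 200, n_pop2 = 200, n_chrom = 2,
                      n_snps_per_chrom = 100, n_qtl = 10, ne_drift = 50,
                      generations_split = gens, rho_adjacent = 0.9,
                      seed = 31, missing_geno_rate = 0)
    pool <- simulate_ancestral_haplotypes(cfg)
    drift <- split_and_drift(pool, cfg)
    ld1 <- adjacent_ld(drift$geno1, drift$hap1)
    ld2 <- adjacent_ld(drift$geno2, drift$hap2)
    ld_consistency(ld1, ld2)$mean
  })
  expect_gt(cons[1], 0.8)        # same gene pool, sampling noise only
  expect_lt(cons[2], cons[1])    # 30 generations of drift decorrelate phase
  expect_gt(cons[1] - cons[2], 0.15)
})

test_that("pedigrees are topologically valid and populations disjoint", {
  sim <- small_gxe_sim()
  for (ped in list(sim$ped1, sim$ped2)) {
    pos <- seq_len(nrow(ped))
    names(pos) <- ped$id
    for (i in pos) {
      for (par in c(ped$sire[i], ped$dam[i]))
        if (par != "0") expect_lt(pos[[par]], i)
    }
  }
  expect_length(intersect(sim$ped1$id, sim$ped2$id), 0)
  ## genotyped individuals are the final generation of each pedigree
  expect_true(all(sim$geno1$ids %in% sim$ped1$id))
  expect_true(all(sim$geno2$ids %in% sim$ped2$id))
})

test_that("QTL effect correlation converges to rg_env", {
  tr <- default_traits()[1, ]
  tr$rg_env <- 0.65
  cfg <- sim_config(n_chrom = 2, n_snps_per_chrom = 3000, n_qtl = 5000,
                    traits = tr, seed = 13)
  truth <- simulate_qtl_effects(cfg)
  expect_equal(cor(truth$effects[[1]][, 1], truth$effects[[1]][, 2]), 0.65,
               tolerance = 0.03)
})

test_that("degenerate variance config reproduces breeding values exactly", {
  tr <- data.frame(trait = "GT", type = "growth", h2_pop1 = 1, h2_pop2 = 1,
                   repeatability = NA, rg_env = 0.6)
  cfg <- sim_config(n_pop1 = 60, n_pop2 = 40, n_chrom = 2, n_snps_per_chrom = 40,
                    n_qtl = 20, ne_drift = 20, generations_split = 2,
                    traits = tr, litter_var_frac = 0, fixed_var_frac = 0,
                    seed = 5)
  sim <- simulate_gxe(cfg)
  ph <- sim$pheno[sim$pheno$pop == "pop1", ]
  tbv <- sim$truth$tbv$GT$pop1[match(ph$id, sim$truth$tbv_ids$pop1), 1]
  expect_equal(ph$value - 10, tbv, tolerance = 1e-12)
})

test_that("realized variance fractions match the configured budget", {
  sim <- small_gxe_sim()
  rh <- sim$truth$realized_h2
  expect_true(all(abs(rh$realized_h2 - rh$target_h2) <
                    0.05 * pmax(rh$target_h2, 0.5) + 0.02))
  ## repeated records: within-sow correlation tracks the repeatability
  tr <- data.frame(trait = "RT", type = "repro", h2_pop1 = 0.1, h2_pop2 = 0.1,
                   repeatability = 0.2, rg_env = 0.7)
  cfg <- sim_config(n_pop1 = 1500, n_pop2 = 20, n_chrom = 2,
                    n_snps_per_chrom = 50, n_qtl = 30, ne_drift = 40,
                    generations_split = 2, traits = tr, n_parities = 2,
                    fixed_var_frac = 0, seed = 23)
  sim2 <- simulate_gxe(cfg)
  ph <- sim2$pheno[sim2$pheno$pop == "pop1", ]
  w <- reshape(ph[, c("id", "parity", "value")], direction = "wide",
               idvar = "id", timevar = "parity")
  expect_lt(abs(cor(w[[2]], w[[3]]) - 0.2), 0.06)
})

test_that("dataset writers round-trip and truth JSON is readable", {
  sim <- fixture("tiny_sim", function()
    simulate_gxe(sim_config(n_pop1 = 25, n_pop2 = 15, n_chrom = 2,
                            n_snps_per_chrom = 20, n_qtl = 8, ne_drift = 12,
                            generations_split = 2, seed = 3,
                            missing_geno_rate = 0.05)))
  td <- withr::local_tempdir()
  write_sim_dataset(sim, td)
  g1 <- read_genotypes(file.path(td, "pop1"), "plink_text")
  expect_equal(unname(g1$dosages) * 1, unname(sim$geno1$dosages) * 1)
  g1v <- read_genotypes(file.path(td, "pop1.vcf"), "vcf")
  expect_equal(unname(g1v$dosages) * 1, unname(sim$geno1$dosages) * 1)
  truth <- jsonlite::read_json(file.path(td, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$qtl_indices, sim$truth$qtl_indices)
  ped <- read.csv(file.path(td, "pedigree_pop1.csv"), colClasses = "character")
  expect_setequal(ped$id, sim$ped1$id)
})
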