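test_that("LD follows the haplotype-frequency formula", {
  ## hand-count oracle: 8 haplotypes, counts AB=3, Ab=1, aB=2, ab=2
  ## f(AB) = 3/8, f(A) = 4/8, f(B) = 5/8
  ## D = 0.375 - 0.5 * 0.625 = 0.0625
  ## r2 = D^2 / (0.5 * 0.5 * 0.625 * 0.375) = 0.06666...
  res <- ld_r2(3 / 8, 4 / 8, 5 / 8)
  expect_equal(res$r2, 1 / 15)
  expect_equal(res$r, sqrt(1 / 15))
  ## linkage equilibrium and complete LD limits
  expect_equal(ld_r2(0.25, 0.5, 0.5)$r2, 0)
  expect_equal(ld_r2(0.5, 0.5, 0.5)$r2, 1)
  ## r carries the sign of D
  expect_lt(ld_r2(0.1, 0.5, 0.5)$r, 0)
})

test_that("formula r2 equals squared haplotype-indicator correlation", {
  set.seed(42)
  for (case in 1:20) {
    n_hap <- 2 * sample(20:60, 1)
    h1 <- rbinom(n_hap, 1, runif(1, 0.2, 0.8))
    h2 <- ifelse(runif(n_hap) < 0.7, h1, rbinom(n_hap, 1, 0.5))
    if (var(h1) == 0 || var(h2) == 0) next
    res <- ld_r2(mean(h1 & h2), mean(h1), mean(h2))
    expect_equal(res$r2, cor(h1, h2)^2, tolerance = 1e-12)
    expect_equal(res$r, cor(h1, h2), tolerance = 1e-12)
  }
})

test_that("adjacent_ld uses phase when available and EM otherwise", {
  sim <- small_gxe_sim()
  g <- impute_missing(sim$geno1, "mean_dosage")
  ld_ph <- adjacent_ld(sim$geno1, sim$hap1)
  ld_em <- adjacent_ld(g)
  use <- ld_ph$pairs$used & ld_em$pairs$used
  ## EM from unphased genotypes closely tracks the true-phase statistic
  expect_gt(cor(ld_ph$pairs$r[use], ld_em$pairs$r[use]), 0.9)
  ## pairs are within-chromosome only
  expect_true(all(table(ld_ph$pairs$chr) ==
                    table(sim$map$chr)[as.character(unique(ld_ph$pairs$chr))] - 1))
})

test_that("ld_consistency is symmetric, exact on self, and sign-aware", {
  sim <- small_gxe_sim()
  ld1 <- adjacent_ld(sim$geno1, sim$hap1)
  ld2 <- adjacent_ld(sim$geno2, sim$hap2)
  expect_equal(ld_consistency(ld1, ld1)$mean, 1)
  expect_equal(ld_consistency(ld1, ld2)$mean, ld_consistency(ld2, ld1)$mean)
  neg <- ld1
  neg$pairs$r <- -neg$pairs$r
  expect_equal(ld_consistency(ld1, neg)$mean, -1)
  ## mismatched pair lists rejected
  expect_error(ld_consistency(ld1, adjacent_ld(subset_genotypes(
    sim$geno2, markers = 2:nrow(sim$map)))), "different marker-pair")
})

test_that("QC filters straddle their thresholds and report counts", {
  set.seed(9)
  n <- 200
  ## markers engineered around the MAF threshold: expected MAF 0.049 / 0.051
  d <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3), rbinom(n, 2, 0.3))
  d[, 2] <- rbinom(n, 2, 0.5)
  g <- genotype_matrix(d, data.frame(chr = 1, pos = 1:3 * 100, name = paste0("m", 1:3)))
  maf <- pmin(colMeans(d) / 2, 1 - colMeans(d) / 2)
  out <- qc_filter(g, maf_min = maf[1] + 1e-9)
  expect_false("m1" %in% out$genos$map$name)
  expect_true("m2" %in% out$genos$map$name)
  out2 <- qc_filter(g, maf_min = maf[1] - 1e-9)
  expect_true("m1" %in% out2$genos$map$name)

  ## HWE: counts (81, 18, 1) at p(A) = 0.9 sit exactly at expectation
  d_hwe <- matrix(rep(c(0, 1, 2), c(81, 18, 1)))
  g_hwe <- genotype_matrix(d_hwe, data.frame(chr = 1, pos = 1, name = "h"),
                           ids = sprintf("x%03d", 1:100))
  expect_equal(unname(gxepred:::hwe_pvalues(d_hwe)), 1)
  expect_equal(qc_filter(g_hwe, maf_min = 0)$report$n_markers_out, 1L)

  ## all animals below the reliability bound: empty result, not an error
  rel <- setNames(rep(0.29, nrow(d)), g$ids)
  out3 <- qc_filter(g, reliabilities = rel)
  expect_equal(out3$report$n_individuals_out, 0L)
  expect_equal(out3$report$removed_by_rule[["reliability"]], nrow(d))
  expect_error(qc_filter(g, reliabilities = rel[1:3]), "missing")
})

test_that("QC is idempotent", {
  sim <- small_gxe_sim()
  q1 <- qc_filter(sim$geno1)
  q2 <- qc_filter(q1$genos)
  expect_equal(q2$report$n_markers_in, q2$report$n_markers_out)
  expect_equal(q2$report$n_individuals_in, q2$report$n_individuals_out)
})

test_that("imputation fills missing calls per its contract", {
  d <- matrix(c(0, 1, NA, 2, NA, 1), 3, 2)
  g <- genotype_matrix(d, data.frame(chr = 1, pos = 1:2, name = c("a", "b")),
                       ids = c("i1", "i2", "i3"))
  ## mean dosage = 2p from observed calls
  gi <- impute_missing(g, "mean_dosage")
  expect_false(anyNA(gi$dosages))
  expect_equal(gi$dosages[3, 1], 2 * mean(d[1:2, 1]) / 2)
  ## p = 0.5 inserts exactly 1
  d2 <- matrix(c(0, 2, NA), 3, 1)
  g2 <- genotype_matrix(d2, data.frame(chr = 1, pos = 1, name = "a"),
                        ids = c("i1", "i2", "i3"))
  expect_equal(impute_missing(g2, "mean_dosage")$dosages[3, 1], 1)
  ## no-missing input is returned unchanged
  gi2 <- impute_missing(gi, "freq_draw")
  expect_identical(gi2$dosages, gi$dosages)
  ## freq_draw respects Hardy-Weinberg proportions
  set.seed(1)
  n <- 4e4
  d3 <- matrix(c(rep(NA, n), rbinom(20, 2, 0.3)), ncol = 1)
  g3 <- genotype_matrix(d3, data.frame(chr = 1, pos = 1, name = "a"),
                        ids = sprintf("z%05d", seq_len(n + 20)))
  p <- mean(d3[, 1], na.rm = TRUE) / 2
  gd <- impute_missing(g3, "freq_draw", seed = 4)
  tab <- table(factor(gd$dosages[seq_len(n), 1], 0:2)) / n
  expect_equal(unname(c(tab)), c((1 - p)^2, 2 * p * (1 - p), p^2),
               tolerance = 0.02)
  ## all-missing marker is an error
  d4 <- matrix(NA_real_, 3, 1)
  g4 <- genotype_matrix(d4, data.frame(chr = 1, pos = 1, name = "a"),
                        ids = c("i1", "i2", "i3"))
  expect_error(impute_missing(g4), "cannot be imputed")
})

test_that("GRM matches the VanRaden construction", {
  ## 3 individuals x 2 markers hand oracle at p = (0.5, 0.5):
  ## Z = [[-1, 1], [1, -1], [0, 0]], denom = 2 * (0.25 + 0.25) = 1
  d <- matrix(c(0, 2, 1, 2, 0, 1), 3, 2)
  g <- genotype_matrix(d, data.frame(chr = 1, pos = 1:2, name = c("a", "b")),
                       ids = c("i1", "i2", "i3"))
  grm <- make_grm(g)
  expect_equal(grm$denominator, 1)
  expect_equal(unname(grm$matrix),
               matrix(c(2, -2, 0, -2, 2, 0, 0, 0, 0), 3, 3))
  ## constant heterozygote at p = 0.5 centers to zero
  d1 <- matrix(1, 4, 3)
  g1 <- genotype_matrix(d1, data.frame(chr = 1, pos = 1:3, name = paste0("m", 1:3)),
                        ids = paste0("i", 1:4))
  expect_equal(unname(make_grm(g1, freq = rep(0.5, 3))$matrix),
               matrix(0, 4, 4))
  ## identical genomes: off-diagonal equals both diagonals
  gg <- random_genotypes(5, 50, seed = 3)
  gg$dosages[2, ] <- gg$dosages[1, ]
  grm2 <- make_grm(gg)
  expect_equal(grm2$matrix[1, 2], grm2$matrix[1, 1])
  expect_equal(grm2$matrix[1, 2], grm2$matrix[2, 2])
  ## permutation invariance
  g5 <- random_genotypes(8, 60, seed = 5)
  perm <- sample(8)
  grm_a <- make_grm(g5)
  grm_b <- make_grm(subset_genotypes(g5, g5$ids[perm]))
  expect_equal(unname(grm_b$matrix), unname(grm_a$matrix[perm, perm]))
  ## monomorphic panel has no denominator
  dmono <- matrix(2, 3, 2)
  gmono <- genotype_matrix(dmono, data.frame(chr = 1, pos = 1:2,
                                             name = c("a", "b")),
                           ids = paste0("i", 1:3))
  expect_error(make_grm(gmono), "monomorphic")
})

test_that("PCA of the GRM has the documented eigenstructure", {
  ## identity: equal variance explained
  p <- pca_grm(diag(4), k = 4)
  expect_equal(p$variance_explained, rep(0.25, 4))
  ## two-block matrix: PC1 separates blocks with opposite signs
  b <- matrix(0, 6, 6)
  b[1:3, 1:3] <- 0.5; b[4:6, 4:6] <- 0.5
  diag(b) <- 1
  p2 <- pca_grm(b, k = 2)
  expect_true(all(sign(p2$vectors[1:3, 1]) != sign(p2$vectors[4:6, 1])))
  ## eigenvalue sum equals the trace; sign convention is deterministic
  g <- make_grm(random_genotypes(30, 100, seed = 8))
  p3 <- pca_grm(g, k = 30)
  expect_equal(sum(p3$values), sum(diag(g$matrix)), tolerance = 1e-8)
  expect_true(all(apply(p3$vectors, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_error(pca_grm(diag(3), k = 4), "dimension")
})

test_that("VCF reader agrees with VariantAnnotation on the same file", {
  sim <- fixture("tiny_sim", function()
    simulate_gxe(sim_config(n_pop1 = 25, n_pop2 = 15, n_chrom = 2,
                            n_snps_per_chrom = 20, n_qtl = 8, ne_drift = 12,
                            generations_split = 2, seed = 3,
                            missing_geno_rate = 0.05)))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$geno1, path)
  ours <- read_genotypes(path, "vcf")
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  gt <- VariantAnnotation::geno(v)$GT
  lut <- c("0/0" = 0, "0/1" = 1, "1/1" = 2, "./." = NA)
  theirs <- t(matrix(lut[gt], nrow(gt), ncol(gt)))
  expect_equal(unname(ours$dosages) * 1, unname(theirs) * 1)
})

test_that("malformed genotype files raise informative errors", {
  g <- random_genotypes(4, 3, seed = 1)
  td <- withr::local_tempdir()
  write_plink(g, file.path(td, "ok"))
  ## duplicated id
  lines <- readLines(file.path(td, "ok.ped"))
  lines[2] <- lines[1]
  writeLines(lines, file.path(td, "dup.ped"))
  file.copy(file.path(td, "ok.map"), file.path(td, "dup.map"))
  expect_error(read_genotypes(file.path(td, "dup"), "plink_text"), "duplicated")
  ## bad allele code names the line
  lines2 <- readLines(file.path(td, "ok.ped"))
  lines2[3] <- sub(" 1 ", " 7 ", lines2[3])
  writeLines(lines2, file.path(td, "bad.ped"))
  file.copy(file.path(td, "ok.map"), file.path(td, "bad.map"))
  expect_error(read_genotypes(file.path(td, "bad"), "plink_text"), "line 3")
})
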