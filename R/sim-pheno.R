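## Phenotype simulation and the one-stop dataset generator.

## Per-population, per-trait record generator.  The phenotypic variance is
## set from the realized additive variance of the recorded animals and the
## configured heritability; litter / permanent-environment / residual
## variances fill the remaining budget.  Returns the records plus the
## realized variance components of the drawn deviates.
sim_trait_records <- function(trait_row, ids, sex, litter_grp, tbv, cfg) {
  h2 <- trait_row$h2
  type <- trait_row$type
  var_a <- var(tbv)
  if (h2 <= 0 || var_a <= 0) {
    tbv <- tbv * 0
    var_a <- 0
    var_p <- 1
  } else var_p <- var_a / h2
  lev <- cfg$fixed_effect_levels
  fx_var <- cfg$fixed_var_frac * var_p
  herd_eff <- rnorm(lev[["herd"]], 0, sqrt(fx_var))
  year_eff <- rnorm(lev[["year"]], 0, sqrt(fx_var))
  season_eff <- rnorm(lev[["season"]], 0, sqrt(fx_var))
  n <- length(ids)
  if (type == "growth") {
    sex_eff <- rnorm(2, 0, sqrt(fx_var))
    var_l <- cfg$litter_var_frac * var_p
    var_e <- max(var_p - var_a - var_l, 0)
    lit_levels <- unique(litter_grp)
    lit_dev <- setNames(rnorm(length(lit_levels), 0, sqrt(var_l)), lit_levels)
    herd <- sample.int(lev[["herd"]], n, replace = TRUE)
    year <- sample.int(lev[["year"]], n, replace = TRUE)
    season <- sample.int(lev[["season"]], n, replace = TRUE)
    e <- rnorm(n, 0, sqrt(var_e))
    l <- unname(lit_dev[litter_grp])
    val <- 10 + herd_eff[herd] + year_eff[year] + season_eff[season] +
      sex_eff[sex + 1L] + l + tbv + e
    rec <- data.frame(id = ids, trait = trait_row$trait, value = val,
                      herd = herd, year = year, season = season,
                      sex = sex, litter = litter_grp, parity = NA_integer_,
                      stringsAsFactors = FALSE)
    comps <- c(additive = var_a, group = var(l), residual = var(e))
  } else {
    rep_t <- trait_row$repeatability
    if (is.na(rep_t)) stop("repeatability required for reproduction trait ",
                           trait_row$trait)
    var_pe <- max(rep_t - h2, 0) * var_p
    var_e <- max((1 - rep_t) * var_p, 0)
    sows <- which(sex == 0)
    np <- cfg$n_parities
    pe <- rnorm(length(sows), 0, sqrt(var_pe))
    idx <- rep(seq_along(sows), each = np)
    nr <- length(idx)
    herd <- sample.int(lev[["herd"]], length(sows), replace = TRUE)[idx]
    year <- sample.int(lev[["year"]], nr, replace = TRUE)
    season <- sample.int(lev[["season"]], nr, replace = TRUE)
    e <- rnorm(nr, 0, sqrt(var_e))
    val <- 10 + herd_eff[herd] + year_eff[year] + season_eff[season] +
      pe[idx] + tbv[sows][idx] + e
    rec <- data.frame(id = ids[sows][idx], trait = trait_row$trait, value = val,
                      herd = herd, year = year, season = season,
                      sex = 0L, litter = NA_character_,
                      parity = rep(seq_len(np), times = length(sows)),
                      stringsAsFactors = FALSE)
    comps <- c(additive = var(tbv[sows]), group = var(pe), residual = var(e))
  }
  list(records = rec, comps = comps)
}

#' Simulate phenotype records for a drifted two-population dataset
#'
#' Growth traits receive one record per recorded individual with herd,
#' year, season and sex fixed-effect levels and a common-litter random
#' deviate (litters are the true full-sib families of the simulated
#' pedigree).  Reproduction traits receive `n_parities` records per sow
#' (females only) with a permanent-environment deviate shared across
#' parities.  True breeding values are the dosage-weighted sums of the
#' environment-specific QTL effects, scaled so that realized heritability
#' and repeatability match the configuration within sampling error.
#'
#' @param drift a [split_and_drift] result
#' @param truth a [simulate_qtl_effects] result
#' @param cfg the [sim_config]
#' @return list with `pheno` (data.frame: id, pop, trait, value, herd,
#'   year, season, sex, litter, parity) and `truth` (the input truth
#'   augmented with per-trait true breeding values for both environments,
#'   realized variance fractions and realized effect correlations).
#' @export
simulate_phenotypes <- function(drift, truth, cfg) {
  if (max(truth$qtl_indices) > nrow(drift$map))
    stop("truth refers to markers outside the genotype map")
  if (!all(cfg$traits$trait %in% names(truth$effects)))
    stop("trait requested without a matching effects entry")
  set.seed(sim_seeds(cfg)[4])
  qtl <- truth$qtl_indices
  dos_at <- function(h, cols) {
    n <- nrow(h) / 2L
    h[2L * seq_len(n) - 1L, cols, drop = FALSE] +
      h[2L * seq_len(n), cols, drop = FALSE]
  }
  qd <- list(dos_at(drift$hap_ped1, qtl), dos_at(drift$hap_ped2, qtl))
  ped_ids <- list(drift$hap_ped_ids1, drift$hap_ped_ids2)
  peds <- list(drift$ped1, drift$ped2)
  records <- list(); tbvs <- list(); r_h2 <- list()
  for (t in seq_len(nrow(cfg$traits))) {
    tr <- cfg$traits[t, ]
    eff <- truth$effects[[tr$trait]]
    tbv_t <- list()
    for (p in 1:2) {
      ped <- peds[[p]]
      stopifnot(identical(ped$id, ped_ids[[p]]))
      tbv_both <- qd[[p]] %*% eff          # n_ped x 2 environments
      tbv_both <- sweep(tbv_both, 2, colMeans(tbv_both))
      own <- tbv_both[, p]
      litter_grp <- ifelse(ped$dam == "0", paste0("self_", ped$id),
                           paste0("lit_", ped$dam))
      row <- data.frame(trait = tr$trait, type = tr$type,
                        h2 = if (p == 1) tr$h2_pop1 else tr$h2_pop2,
                        repeatability = tr$repeatability,
                        stringsAsFactors = FALSE)
      out <- sim_trait_records(row, ped$id, ped$sex, litter_grp, own, cfg)
      out$records$pop <- ped$pop[1]
      records[[length(records) + 1]] <- out$records
      tbv_t[[p]] <- tbv_both
      r_h2[[length(r_h2) + 1]] <-
        data.frame(trait = tr$trait, pop = ped$pop[1],
                   realized_h2 = unname(out$comps["additive"] / sum(out$comps)),
                   target_h2 = row$h2)
    }
    tbvs[[tr$trait]] <- list(pop1 = tbv_t[[1]], pop2 = tbv_t[[2]])
  }
  pheno <- do.call(rbind, records)
  pheno <- pheno[, c("id", "pop", "trait", "value", "herd", "year",
                     "season", "sex", "litter", "parity")]
  rownames(pheno) <- NULL
  truth$tbv <- tbvs
  truth$tbv_ids <- list(pop1 = ped_ids[[1]], pop2 = ped_ids[[2]])
  truth$realized_rg <- vapply(truth$effects, function(e) cor(e[, 1], e[, 2]),
                              numeric(1))
  truth$realized_h2 <- do.call(rbind, r_h2)
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete two-population G x E dataset
#'
#' Runs the full generator: ancestral pool, split-and-drift, QTL effects
#' and phenotype records.  The configuration seed fully determines the
#' output.
#'
#' @param cfg a [sim_config]
#' @return a `gxe_sim` object: list with `cfg`, `geno1`, `geno2`, `ped1`,
#'   `ped2`, `hap1`, `hap2` (phased haplotypes of the genotyped
#'   generation), `pheno`, `truth` and `map`.
#' @export
simulate_gxe <- function(cfg = sim_config()) {
  pool <- simulate_ancestral_haplotypes(cfg)
  drift <- split_and_drift(pool, cfg)
  truth <- simulate_qtl_effects(cfg, n_markers = nrow(pool$map))
  ph <- simulate_phenotypes(drift, truth, cfg)
  out <- list(cfg = cfg, geno1 = drift$geno1, geno2 = drift$geno2,
              ped1 = drift$ped1, ped2 = drift$ped2,
              hap1 = drift$hap1, hap2 = drift$hap2,
              pheno = ph$pheno, truth = ph$truth, map = drift$map)
  if (cfg$mask_qtl) {
    keep <- setdiff(seq_len(nrow(drift$map)), ph$truth$qtl_indices)
    out$geno1 <- subset_genotypes(out$geno1, markers = keep)
    out$geno2 <- subset_genotypes(out$geno2, markers = keep)
    out$hap1 <- out$hap1[, keep, drop = FALSE]
    out$hap2 <- out$hap2[, keep, drop = FALSE]
  }
  class(out) <- "gxe_sim"
  out
}

#' @export
print.gxe_sim <- function(x, ...) {
  cat("two-population G x E simulation\n")
  cat("  pop1:", length(x$geno1$ids), "genotyped;  pop2:", length(x$geno2$ids),
      "genotyped;", nrow(x$map), "markers\n")
  cat("  traits:", paste(x$cfg$traits$trait, collapse = ", "),
      " phenotype records:", nrow(x$pheno), "\n")
  invisible(x)
}

#' Write a simulated dataset as plain-text files
#'
#' Writes PLINK and VCF genotypes per population, a phenotype CSV
#' (columns: id, pop, trait, value, herd, year, season, sex, litter,
#' parity), pedigree CSVs (id, sire, dam; 0 = unknown) and a truth JSON
#' with QTL indices and effects.
#'
#' @param sim a [simulate_gxe] result
#' @param dir output directory (created if needed)
#' @return invisibly, the output directory.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(sim$geno1, file.path(dir, "pop1"))
  write_plink(sim$geno2, file.path(dir, "pop2"))
  write_vcf(sim$geno1, file.path(dir, "pop1.vcf"))
  write_vcf(sim$geno2, file.path(dir, "pop2.vcf"))
  write.csv(sim$pheno, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  write.csv(sim$ped1[, c("id", "sire", "dam")], file.path(dir, "pedigree_pop1.csv"),
            row.names = FALSE)
  write.csv(sim$ped2[, c("id", "sire", "dam")], file.path(dir, "pedigree_pop2.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(qtl_indices = sim$truth$qtl_indices,
         effects = lapply(sim$truth$effects, function(e)
           list(env1 = unname(e[, 1]), env2 = unname(e[, 2]))),
         realized_rg = as.list(sim$truth$realized_rg)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
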