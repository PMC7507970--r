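#' Default trait panel for the two-population simulation
#'
#' Four traits typical of a Yorkshire pig evaluation: two growth traits
#' (AGE, days to 100 kg; BFT, backfat at 100 kg) with single records and a
#' common-litter effect, and two reproduction traits (NBA, piglets born
#' alive; TNB, total born) with repeated sow records and a
#' permanent-environment effect.  Heritabilities per population and the
#' between-environment genetic correlations default to the magnitudes
#' observed in field Yorkshire data (growth 0.33-0.44, reproduction
#' 0.07-0.11, genetic correlations 0.62-0.72); repeatability of the
#' reproduction traits is set to 0.18, a conventional value for litter
#' size.
#'
#' @return data.frame with one row per trait (columns: trait, type,
#'   h2_pop1, h2_pop2, repeatability, rg_env).
#' @export
default_traits <- function() {
  data.frame(
    trait = c("AGE", "BFT", "NBA", "TNB"),
    type = c("growth", "growth", "repro", "repro"),
    h2_pop1 = c(0.33, 0.34, 0.07, 0.08),
    h2_pop2 = c(0.42, 0.44, 0.09, 0.11),
    repeatability = c(NA, NA, 0.18, 0.18),
    rg_env = c(0.618, 0.623, 0.714, 0.723),
    stringsAsFactors = FALSE)
}

#' Configuration of the two-population G x E simulation
#'
#' The defaults describe the emulated study system: two pig populations of
#' 1,732 and 956 genotyped individuals (the growth-trait counts) with a
#' shared ancestral gene pool but no pedigree links, 18 autosomes carrying
#' a dense SNP panel (about 41 kb mean adjacent spacing), strong
#' within-population adjacent-marker LD, and causal loci whose allele
#' substitution effects are correlated between the two environments
#' (`rg_env` per trait, all below the 0.8 G x E threshold).
#'
#' @param n_pop1,n_pop2 genotyped individuals in the final generation of
#'   each population
#' @param n_chrom number of autosomes
#' @param n_snps_per_chrom markers per autosome
#' @param n_qtl number of causal loci drawn among the genotyped markers
#' @param ne_drift breeding individuals per generation during the drift
#'   phase (effective size knob; smaller values drift LD apart faster)
#' @param generations_split discrete generations of independent random
#'   mating after the ancestral split
#' @param generations_ancestral drift generations of the single common
#'   ancestral population before the split; creates the shared LD pattern
#'   that makes the between-population LD consistency finite
#' @param rho_adjacent first-order latent (Gaussian copula) correlation of
#'   adjacent loci in the ancestral pool; controls within-population
#'   adjacent-pair LD.  Must lie in [0, 1).
#' @param traits trait table as produced by [default_traits()]
#' @param n_parities records per sow for reproduction traits
#' @param fixed_effect_levels named integer vector of level counts for the
#'   herd, year and season fixed effects
#' @param litter_var_frac common-litter variance as a fraction of the
#'   phenotypic variance for growth traits
#' @param fixed_var_frac variance of the drawn fixed-effect level means, as
#'   a fraction of the phenotypic variance (per factor)
#' @param mean_adjacent_bp mean adjacent-marker distance in base pairs
#' @param morgans_per_chrom genetic length of each autosome used by the
#'   one-crossover-per-Morgan recombination model
#' @param missing_geno_rate fraction of genotype calls masked as missing
#' @param mask_qtl if TRUE, causal loci are removed from the delivered
#'   marker panel (hidden-QTL regime); by default they stay visible
#' @param seed integer; fully determines the simulated dataset
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_pop1 = 1732, n_pop2 = 956,
                       n_chrom = 18, n_snps_per_chrom = 3136,
                       n_qtl = 200, ne_drift = 100, generations_split = 30,
                       generations_ancestral = 50, rho_adjacent = 0.96,
                       traits = default_traits(),
                       n_parities = 3,
                       fixed_effect_levels = c(herd = 3, year = 5, season = 4),
                       litter_var_frac = 0.08, fixed_var_frac = 0.10,
                       mean_adjacent_bp = 41000, morgans_per_chrom = 1,
                       missing_geno_rate = 0.01, mask_qtl = FALSE, seed = 1) {
  cfg <- list(n_pop1 = n_pop1, n_pop2 = n_pop2, n_chrom = n_chrom,
              n_snps_per_chrom = n_snps_per_chrom, n_qtl = n_qtl,
              ne_drift = ne_drift, generations_split = generations_split,
              generations_ancestral = generations_ancestral,
              rho_adjacent = rho_adjacent, traits = traits,
              n_parities = n_parities,
              fixed_effect_levels = fixed_effect_levels,
              litter_var_frac = litter_var_frac,
              fixed_var_frac = fixed_var_frac,
              mean_adjacent_bp = mean_adjacent_bp,
              morgans_per_chrom = morgans_per_chrom,
              missing_geno_rate = missing_geno_rate,
              mask_qtl = mask_qtl, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_pop1 >= 2, n_pop2 >= 2, n_chrom >= 1, n_snps_per_chrom >= 2,
              ne_drift >= 4, generations_split >= 0,
              generations_ancestral >= 0, n_parities >= 1,
              litter_var_frac >= 0, fixed_var_frac >= 0,
              missing_geno_rate >= 0, missing_geno_rate < 1)
    if (rho_adjacent < 0 || rho_adjacent >= 1)
      stop("rho_adjacent must lie in [0, 1)")
    if (n_qtl > n_chrom * n_snps_per_chrom)
      stop("n_qtl exceeds the total marker count")
    h2 <- c(traits$h2_pop1, traits$h2_pop2)
    if (any(h2 < 0 | h2 > 1)) stop("heritabilities must lie in [0, 1]")
    rep_ok <- is.na(traits$repeatability) |
      (traits$repeatability >= pmax(traits$h2_pop1, traits$h2_pop2) &
         traits$repeatability <= 1)
    if (!all(rep_ok))
      stop("repeatability must be >= h2 (both populations) and <= 1")
    if (any(traits$rg_env < -1 | traits$rg_env > 1))
      stop("rg_env must lie in [-1, 1]")
    if (any(traits$type == "growth" &
            (traits$h2_pop1 + litter_var_frac > 1 |
               traits$h2_pop2 + litter_var_frac > 1)))
      stop("h2 + litter_var_frac must not exceed 1 for growth traits")
  })
  invisible(cfg)
}

## Deterministic per-stage seeds derived from cfg$seed so that each stage of
## the simulation can also be run standalone without stream coupling.
sim_seeds <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  sample.int(.Machine$integer.max - 1L, 8L)
}
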