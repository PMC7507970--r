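#' Corrected phenotypes for both populations of a simulated dataset
#'
#' Runs the conventional pedigree evaluation separately per population for
#' one trait -- REML variance components (unless supplied), mixed-model
#' equations, and `y_c = EBV + (mean) residual` -- and returns the
#' corrected phenotypes of the genotyped individuals.
#'
#' @param sim a [simulate_gxe] result
#' @param trait trait name present in `sim$pheno`
#' @param vc optional list of per-population variance components (named
#'   `pop1`, `pop2`); skips REML when supplied
#' @return list with `yc` (data.frame: id, pop, yc, restricted to
#'   genotyped individuals), `vc` (per population [reml_estimate] results
#'   or the supplied components) and `fits` (per population
#'   [solve_mme] fits).
#' @export
yc_pipeline <- function(sim, trait, vc = NULL) {
  type <- sim$cfg$traits$type[match(trait, sim$cfg$traits$trait)]
  if (is.na(type)) stop("unknown trait: ", trait)
  model <- ped_model(trait, type)
  out_yc <- list(); out_vc <- list(); fits <- list()
  for (p in c("pop1", "pop2")) {
    ped <- pedigree(if (p == "pop1") sim$ped1 else sim$ped2)
    ph <- sim$pheno[sim$pheno$pop == p, , drop = FALSE]
    if (is.null(vc)) {
      est <- reml_estimate(model, ph, ped)
      vcp <- est$vc
      out_vc[[p]] <- est
    } else {
      vcp <- vc[[p]]
      out_vc[[p]] <- vcp
    }
    fit <- solve_mme(model, ph, ped, vcp, compute_pev = FALSE)
    yc <- corrected_phenotypes(fit)
    genotyped <- if (p == "pop1") sim$geno1$ids else sim$geno2$ids
    yc <- yc[yc$id %in% genotyped, , drop = FALSE]
    yc$pop <- p
    out_yc[[p]] <- yc[, c("id", "pop", "yc")]
    fits[[p]] <- fit
  }
  list(yc = do.call(rbind, out_yc), vc = out_vc, fits = fits)
}
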