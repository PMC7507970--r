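#' Genotype quality control
#'
#' Marker filters: minor allele frequency, call frequency and a 1-df
#' Hardy-Weinberg chi-square test.  Individual filters: genotype call rate
#' and, when supplied, the reliability of the conventional (pedigree) EBV.
#' Thresholds default to the standard panel-QC values used in pig genomic
#' evaluation: MAF >= 0.05, marker call frequency >= 0.90, HWE p >= 1e-7,
#' animal call rate >= 0.90, EBV reliability >= 0.3.
#'
#' Markers are tested on the individuals that survive the individual
#' filters; removing everything is a legal outcome, not an error.
#'
#' @param genos a [genotype_matrix]
#' @param maf_min minimum minor allele frequency
#' @param call_freq_min minimum per-marker call frequency
#' @param hwe_p_min minimum Hardy-Weinberg equilibrium p-value (1-df
#'   chi-square on genotype counts)
#' @param animal_call_rate_min minimum per-individual call rate
#' @param reliability_min minimum EBV reliability; only applied when
#'   `reliabilities` is supplied
#' @param reliabilities optional named numeric vector of per-individual EBV
#'   reliabilities (names = ids)
#' @return list with elements `genos` (filtered [genotype_matrix]) and
#'   `report` (a `qc_report` with in/out counts and per-rule removals).
#' @export
qc_filter <- function(genos, maf_min = 0.05, call_freq_min = 0.90,
                      hwe_p_min = 1e-7, animal_call_rate_min = 0.90,
                      reliability_min = 0.3, reliabilities = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_freq_min >= 0, call_freq_min <= 1,
            animal_call_rate_min >= 0, animal_call_rate_min <= 1)
  d <- genos$dosages
  n_ind_in <- nrow(d); n_mark_in <- ncol(d)

  ## individual filters first (they define the marker-test sample)
  call_rate_ind <- rowMeans(!is.na(d))
  drop_callrate <- call_rate_ind < animal_call_rate_min
  drop_rel <- rep(FALSE, n_ind_in)
  if (!is.null(reliabilities)) {
    rel <- reliabilities[genos$ids]
    if (anyNA(rel)) stop("reliabilities missing for some individuals")
    drop_rel <- rel < reliability_min
  }
  keep_ind <- !(drop_callrate | drop_rel)
  d2 <- d[keep_ind, , drop = FALSE]

  n_kept <- nrow(d2)
  if (n_kept > 0) {
    p <- colMeans(d2, na.rm = TRUE) / 2
    p[is.nan(p)] <- NA
    maf <- pmin(p, 1 - p)
    call_freq <- colMeans(!is.na(d2))
    hwe_p <- hwe_pvalues(d2)
    fail_maf <- is.na(maf) | maf < maf_min
    fail_call <- call_freq < call_freq_min
    fail_hwe <- hwe_p < hwe_p_min
  } else {
    fail_maf <- fail_call <- fail_hwe <- rep(TRUE, n_mark_in)
  }
  keep_mark <- !(fail_maf | fail_call | fail_hwe)

  out <- structure(list(
    n_individuals_in = n_ind_in, n_individuals_out = sum(keep_ind),
    n_markers_in = n_mark_in, n_markers_out = sum(keep_mark),
    removed_by_rule = c(maf = sum(fail_maf), call_freq = sum(fail_call),
                        hwe = sum(fail_hwe),
                        animal_call_rate = sum(drop_callrate),
                        reliability = sum(drop_rel))),
    class = "qc_report")

  g2 <- genotype_matrix(d2[, keep_mark, drop = FALSE],
                        genos$map[keep_mark, , drop = FALSE],
                        pop = genos$pop[keep_ind],
                        ids = genos$ids[keep_ind])
  list(genos = g2, report = out)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC:", x$n_individuals_in, "->", x$n_individuals_out,
      "individuals;", x$n_markers_in, "->", x$n_markers_out, "markers\n")
  cat("  removed by rule (overlaps possible):\n")
  for (r in names(x$removed_by_rule))
    cat(sprintf("    %-18s %d\n", r, x$removed_by_rule[[r]]))
  invisible(x)
}

## 1-df chi-square HWE test per marker; monomorphic markers get p = 1.
hwe_pvalues <- function(d) {
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chi2 <- rep(0, length(n))
  poly <- !is.na(p) & p > 0 & p < 1 & n > 0
  chi2[poly] <- (n0[poly] - e0[poly])^2 / e0[poly] +
    (n1[poly] - e1[poly])^2 / e1[poly] +
    (n2[poly] - e2[poly])^2 / e2[poly]
  pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
  pv[!poly] <- 1
  pv
}

#' Impute missing genotype calls
#'
#' Replaces the external phasing/imputation step of a production pipeline
#' with a self-contained single-marker imputation: either the mean dosage
#' `2p` (possibly non-integer) or a random Hardy-Weinberg draw at the
#' observed allele frequency.
#'
#' @param genos a [genotype_matrix]
#' @param mode `"mean_dosage"` or `"freq_draw"`
#' @param seed optional integer seed used for `"freq_draw"`
#' @return a [genotype_matrix] without missing values.
#' @export
impute_missing <- function(genos, mode = c("mean_dosage", "freq_draw"),
                           seed = NULL) {
  mode <- match.arg(mode)
  d <- genos$dosages
  if (!anyNA(d)) return(genos)
  p <- colMeans(d, na.rm = TRUE) / 2
  all_missing <- is.nan(p)
  if (any(all_missing))
    stop("marker(s) with no observed calls cannot be imputed: ",
         paste(head(genos$map$name[all_missing], 3), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  for (j in which(colSums(is.na(d)) > 0)) {
    miss <- which(is.na(d[, j]))
    d[miss, j] <- if (mode == "mean_dosage") 2 * p[j]
                  else rbinom(length(miss), 2, p[j])
  }
  genotype_matrix(d, genos$map, pop = genos$pop, ids = genos$ids)
}
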