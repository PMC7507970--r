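## Linkage-disequilibrium statistics.
##
## LD between two biallelic loci is measured on haplotype frequencies:
##   r_LD  = (f(AB) - f(A) f(B)) / sqrt(f(A) f(a) f(B) f(b))
##   r2_LD = r_LD^2
## When true phase is available (simulated data) the haplotype frequencies
## are counted directly; otherwise they are estimated from unphased
## genotypes by the standard two-locus EM, with the composite
## genotype-correlation as a documented fallback for EM failures.

#' Signed LD and r-squared from haplotype frequencies
#'
#' @param f_ab frequency of the AB haplotype
#' @param f_a frequency of allele A at the first locus
#' @param f_b frequency of allele B at the second locus
#' @return list with `r` (signed, the sign of f(AB) - f(A)f(B)) and `r2`.
#' @export
ld_r2 <- function(f_ab, f_a, f_b) {
  stopifnot(f_a > 0, f_a < 1, f_b > 0, f_b < 1,
            f_ab >= 0, f_ab <= min(f_a, f_b) + 1e-12)
  d <- f_ab - f_a * f_b
  r <- d / sqrt(f_a * (1 - f_a) * f_b * (1 - f_b))
  list(r = r, r2 = r^2)
}

#' LD between adjacent marker pairs
#'
#' Evaluates consecutive marker pairs within each chromosome.  Pairs with a
#' fixed allele (frequency 0 or 1) in the evaluated sample are skipped and
#' counted, not propagated as NaN.
#'
#' @param genos a [genotype_matrix]
#' @param haplotypes optional phased haplotype matrix (2n x markers, 0/1
#'   counted-allele indicators, two consecutive rows per individual).  When
#'   supplied, haplotype frequencies are counted directly.
#' @return an `ld_result`: list with `pairs` (data.frame: chr, name1,
#'   name2, dist_bp, r, r2, used), `by_chr` (per-chromosome mean distance
#'   and mean r2) and `summary` (genome means and skipped-pair count).
#' @export
adjacent_ld <- function(genos, haplotypes = NULL) {
  map <- genos$map
  d <- genos$dosages
  if (!is.null(haplotypes) && nrow(haplotypes) != 2 * nrow(d))
    stop("haplotypes must have two rows per individual")
  res <- vector("list", length(unique(map$chr)))
  k <- 0
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    if (length(idx) < 2) next
    j1 <- idx[-length(idx)]; j2 <- idx[-1]
    r <- rep(NA_real_, length(j1))
    for (t in seq_along(j1)) {
      r[t] <- pair_r(d[, j1[t]], d[, j2[t]],
                     if (!is.null(haplotypes)) haplotypes[, c(j1[t], j2[t])])
    }
    k <- k + 1
    res[[k]] <- data.frame(chr = ch,
                           name1 = map$name[j1], name2 = map$name[j2],
                           dist_bp = map$pos[j2] - map$pos[j1],
                           r = r, r2 = r^2, used = !is.na(r))
  }
  pairs <- do.call(rbind, res[seq_len(k)])
  by_chr <- do.call(rbind, lapply(split(pairs, pairs$chr), function(p) {
    data.frame(chr = p$chr[1], n_pairs = nrow(p), n_used = sum(p$used),
               mean_dist_bp = mean(p$dist_bp),
               mean_r2 = mean(p$r2[p$used]))
  }))
  rownames(by_chr) <- NULL
  structure(list(pairs = pairs, by_chr = by_chr,
                 summary = list(mean_r2 = mean(pairs$r2[pairs$used]),
                                mean_dist_bp = mean(pairs$dist_bp),
                                n_pairs = nrow(pairs),
                                n_skipped = sum(!pairs$used))),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("adjacent-pair LD: %d pairs (%d skipped), mean r2 = %.3f, mean distance = %.1f kb\n",
              x$summary$n_pairs, x$summary$n_skipped, x$summary$mean_r2,
              x$summary$mean_dist_bp / 1000))
  invisible(x)
}

## signed r for one pair; NA when either locus is fixed or estimation fails
pair_r <- function(g1, g2, hap_pair = NULL) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 4) return(NA_real_)
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) return(NA_real_)
  if (!is.null(hap_pair)) {
    fa <- mean(hap_pair[, 1]); fb <- mean(hap_pair[, 2])
    if (fa <= 0 || fa >= 1 || fb <= 0 || fb >= 1) return(NA_real_)
    fab <- mean(hap_pair[, 1] == 1 & hap_pair[, 2] == 1)
    return(ld_r2(fab, fa, fb)$r)
  }
  fab <- em_hap_freq(g1, g2)
  if (is.na(fab)) return(suppressWarnings(cor(g1, g2)))  # composite fallback
  ld_r2(min(max(fab, 0), min(p1, p2)), p1, p2)$r
}

## Two-locus EM for the AB haplotype frequency from unphased genotype
## counts.  Only the double heterozygote is phase-ambiguous.
em_hap_freq <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  n <- length(g1)
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  fab <- p1 * p2
  n_dh <- tab["1", "1"]
  ## fixed contributions of unambiguous genotype classes to the AB count
  fixed_ab <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"]
  for (it in seq_len(max_iter)) {
    ## P(AB/ab) vs P(Ab/aB) for the double het given current freqs
    f_a <- p1 - fab          # f(Ab)
    f_b <- p2 - fab          # f(aB)
    f_o <- 1 - p1 - p2 + fab # f(ab)
    num <- fab * f_o
    den <- num + f_a * f_b
    w <- if (den <= 0) 0.5 else num / den
    fab_new <- (fixed_ab + w * n_dh) / (2 * n)
    if (abs(fab_new - fab) < tol) return(fab_new)
    fab <- fab_new
  }
  fab
}

#' Between-population LD consistency
#'
#' Pearson correlation, per chromosome, of the signed `r_LD` of adjacent
#' marker pairs in two populations, plus the unweighted mean across
#' chromosomes.  Pairs skipped in either population are excluded from
#' both; chromosomes with fewer than 3 usable pairs are reported as NA.
#'
#' @param ld1,ld2 `ld_result` objects over the identical marker-pair list
#' @return list with `by_chr` (data.frame: chr, n_used, consistency) and
#'   `mean` (unweighted mean over defined chromosomes).
#' @export
ld_consistency <- function(ld1, ld2) {
  p1 <- ld1$pairs; p2 <- ld2$pairs
  if (!identical(paste(p1$name1, p1$name2), paste(p2$name1, p2$name2)))
    stop("the two LD results cover different marker-pair lists")
  use <- p1$used & p2$used
  by_chr <- do.call(rbind, lapply(split(seq_len(nrow(p1)), p1$chr), function(i) {
    ch <- p1$chr[i[1]]
    i <- i[use[i]]
    data.frame(chr = ch, n_used = length(i),
               consistency = if (length(i) >= 3) cor(p1$r[i], p2$r[i]) else NA_real_)
  }))
  rownames(by_chr) <- NULL
  list(by_chr = by_chr, mean = mean(by_chr$consistency, na.rm = TRUE))
}
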