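## Replicated cross-validation comparing three reference designs for
## predicting one target population:
##   st_single   - single-trait model, reference = the target population's
##                 other folds only
##   st_combined - single-trait model, reference = other folds plus the
##                 entire second population treated as the same trait
##   mt          - multi-trait model, other folds = trait 1 and the second
##                 population = trait 2 (GEBVs taken for trait 1)
## The validation fold is identical across schemes within a replicate.

#' Random k-fold partition
#'
#' Folds are as equal as possible (sizes differ by at most 1), exhaustive
#' and disjoint, and deterministic per seed.
#'
#' @param ids character vector of individual ids
#' @param k number of folds
#' @param seed integer seed
#' @return named integer vector of fold assignments (1..k).
#' @export
make_folds <- function(ids, k = 5, seed = NULL) {
  if (k <= 1) stop("k must be at least 2")
  if (length(ids) < k) stop("fewer ids than folds")
  if (!is.null(seed)) set.seed(seed)
  f <- rep_len(seq_len(k), length(ids))
  setNames(f[sample.int(length(ids))], ids)
}

#' Prediction accuracy and unbiasedness
#'
#' Accuracy is the Pearson correlation `r(y_c, GEBV)` in the validation
#' set; unbiasedness is the regression coefficient of `y_c` on GEBV,
#' `b = cov(y_c, GEBV) / var(GEBV)` (1 = no inflation or deflation).
#'
#' @param yc_val named corrected phenotypes of the validation animals
#' @param gebv_val named GEBVs for the same animals
#' @return list with `r`, `b`, `n` and `defined` (FALSE when the GEBV
#'   variance is zero).
#' @export
accuracy_and_bias <- function(yc_val, gebv_val) {
  if (!is.null(names(gebv_val)) && !is.null(names(yc_val)))
    gebv_val <- gebv_val[names(yc_val)]
  n <- length(yc_val)
  if (n < 3) stop("at least 3 validation animals are required")
  if (var(gebv_val) <= 0)
    return(list(r = NA_real_, b = NA_real_, n = n, defined = FALSE))
  list(r = cor(yc_val, gebv_val),
       b = cov(yc_val, gebv_val) / var(gebv_val),
       n = n, defined = TRUE)
}

## reference phenotype sets per scheme; hard error on leakage
scheme_reference <- function(scheme, yc_target, yc_other, val_ids) {
  ref_t <- yc_target[setdiff(names(yc_target), val_ids)]
  if (any(val_ids %in% names(ref_t)) ||
      (scheme != "st_single" && any(val_ids %in% names(yc_other))))
    stop("leakage: validation id found in the reference set")
  switch(scheme,
         st_single = list(y = ref_t),
         st_combined = list(y = c(ref_t, yc_other)),
         mt = list(y1 = ref_t, y2 = yc_other),
         stop("unknown scheme: ", scheme))
}

#' Run one prediction scheme for one fold
#'
#' @param scheme `"st_single"`, `"st_combined"` or `"mt"`
#' @param model `"gblup"` or `"bayescpi"`
#' @param fold_val character ids of the held-out fold (target population)
#' @param data list with `yc_target`, `yc_other` (named corrected
#'   phenotypes), `grm_target`, `grm_joint` (for gblup), `geno_target`,
#'   `geno_joint` (imputed genotype matrices, for bayescpi)
#' @param bayes_cfg [bayes_config] used by the bayescpi model
#' @param gblup_init optional AI-REML warm start for the mt scheme
#' @return list with `gebv` (named, the held-out fold), and `fit`.
#' @export
run_scheme <- function(scheme, model, fold_val, data,
                       bayes_cfg = bayes_config(), gblup_init = NULL) {
  ref <- scheme_reference(scheme, data$yc_target, data$yc_other, fold_val)
  if (model == "gblup") {
    fit <- switch(scheme,
      st_single = st_gblup(data$grm_target, ref$y),
      st_combined = st_gblup(data$grm_joint, ref$y),
      mt = mt_gblup(data$grm_joint, ref$y1, ref$y2, init = gblup_init))
    gebv <- if (scheme == "mt") fit$gebv1[fold_val] else fit$gebv[fold_val]
  } else if (model == "bayescpi") {
    fit <- switch(scheme,
      st_single = st_bayescpi(data$geno_target, ref$y, bayes_cfg),
      st_combined = st_bayescpi(data$geno_joint, ref$y, bayes_cfg),
      mt = mt_bayescpi(data$geno_joint, ref$y1, ref$y2, bayes_cfg))
    gebv <- if (scheme == "mt") fit$gebv1[fold_val] else fit$gebv[fold_val]
  } else stop("unknown model: ", model)
  list(gebv = gebv, fit = fit)
}

#' Replicated k-fold cross-validation of the prediction schemes
#'
#' Replicate `r` uses seed `master_seed + r` for its fold split, so every
#' scheme sees exactly the same validation folds within a replicate.
#' Variance components (gblup) are re-estimated within each reference
#' set; the multi-trait AI-REML is warm-started across folds of a
#' replicate.
#'
#' @param geno_joint imputed joint [genotype_matrix] over both populations
#' @param yc data.frame with columns `id`, `pop`, `yc`
#' @param target_pop population label of the prediction target
#' @param schemes subset of `c("st_single", "st_combined", "mt")`
#' @param models subset of `c("gblup", "bayescpi")`
#' @param n_reps replicates
#' @param k folds per replicate
#' @param master_seed integer master seed
#' @param bayes_cfg [bayes_config] for the bayescpi model (per-fold chains
#'   are seeded from the replicate seed)
#' @return a `cv_result`: data.frame of per-(replicate, fold, scheme,
#'   model) accuracy and unbiasedness, with the scheme/model grid in
#'   `attr(, "design")`.
#' @export
run_cv <- function(geno_joint, yc, target_pop,
                   schemes = c("st_single", "st_combined", "mt"),
                   models = "gblup", n_reps = 20, k = 5, master_seed = 1,
                   bayes_cfg = bayes_config()) {
  stopifnot(all(schemes %in% c("st_single", "st_combined", "mt")),
            all(models %in% c("gblup", "bayescpi")))
  yc <- yc[!is.na(yc$yc), , drop = FALSE]
  pops <- unique(yc$pop)
  if (!target_pop %in% pops) stop("target_pop not present in yc$pop")
  other_pop <- setdiff(pops, target_pop)
  if (length(other_pop) != 1) stop("exactly two populations are required")
  yc_target <- setNames(yc$yc[yc$pop == target_pop], yc$id[yc$pop == target_pop])
  yc_other <- setNames(yc$yc[yc$pop == other_pop], yc$id[yc$pop == other_pop])
  keep <- c(names(yc_target), names(yc_other))
  geno_joint <- subset_genotypes(geno_joint, keep)
  geno_target <- subset_genotypes(geno_joint, names(yc_target))
  data <- list(yc_target = yc_target, yc_other = yc_other,
               geno_target = geno_target, geno_joint = geno_joint)
  if ("gblup" %in% models) {
    data$grm_target <- make_grm(geno_target)
    data$grm_joint <- make_grm(geno_joint)
  }
  rows <- list()
  for (rep_i in seq_len(n_reps)) {
    rep_seed <- master_seed + rep_i
    folds <- make_folds(names(yc_target), k, seed = rep_seed)
    mt_init <- NULL
    for (f in seq_len(k)) {
      val <- names(folds)[folds == f]
      for (model in models) for (scheme in schemes) {
        bc <- bayes_cfg
        ## per-(replicate, fold, scheme) chain seed, kept under 2^31
        bc$seed <- (rep_seed %% 1000000L) * 1000L + f * 10L +
          match(scheme, c("st_single", "st_combined", "mt"))
        out <- run_scheme(scheme, model, val, data, bayes_cfg = bc,
                          gblup_init = if (scheme == "mt") mt_init)
        if (model == "gblup" && scheme == "mt") {
          cc <- out$fit$cc
          mt_init <- c(cc$M[1, 1], cc$M[1, 2], cc$M[2, 2], cc$R)
        }
        ab <- accuracy_and_bias(yc_target[val], out$gebv)
        rows[[length(rows) + 1]] <-
          data.frame(replicate = rep_i, fold = f, scheme = scheme,
                     model = model, accuracy = ab$r, unbiasedness = ab$b,
                     n_val = ab$n, defined = ab$defined)
      }
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "design") <- list(target_pop = target_pop, schemes = schemes,
                              models = models, n_reps = n_reps, k = k,
                              master_seed = master_seed)
  class(res) <- c("cv_result", "data.frame")
  res
}

#' Summarize a cross-validation run and test scheme differences
#'
#' Replicate means are the resampling unit: accuracy and unbiasedness are
#' averaged over folds within a replicate, summarized as mean +/- SD over
#' replicates, and scheme pairs are compared by a two-tailed paired t-test
#' on the replicate means.  Significance letters (P < 0.05) are assigned
#' per model, highest mean first.
#'
#' @param res a [run_cv] result
#' @param alpha significance level for the letters
#' @return a `cv_summary`: list with `table` (per model x scheme: mean/SD
#'   of accuracy and unbiasedness plus letters) and `pairwise` (paired
#'   t-test p-values and mean differences).
#' @export
summarize_and_test <- function(res, alpha = 0.05) {
  res <- res[res$defined & !is.na(res$accuracy), , drop = FALSE]
  agg <- aggregate(cbind(accuracy, unbiasedness) ~ replicate + scheme + model,
                   data = res, FUN = mean)
  tabs <- list(); pw <- list()
  for (model in unique(agg$model)) {
    a <- agg[agg$model == model, ]
    schemes <- unique(a$scheme)
    reps <- sort(unique(a$replicate))
    acc <- sapply(schemes, function(s) {
      x <- a[a$scheme == s, ]
      x <- x[match(reps, x$replicate), ]
      x$accuracy
    })
    bias <- sapply(schemes, function(s) {
      x <- a[a$scheme == s, ]
      x <- x[match(reps, x$replicate), ]
      x$unbiasedness
    })
    if (anyNA(acc)) stop("mismatched replicate sets between schemes")
    ## pairwise paired t-tests on replicate means
    pmat <- matrix(1, length(schemes), length(schemes),
                   dimnames = list(schemes, schemes))
    for (i in seq_along(schemes)) for (j in seq_along(schemes)) {
      if (i < j) {
        d <- acc[, i] - acc[, j]
        p <- if (length(reps) >= 2 && sd(d) > 0)
          t.test(acc[, i], acc[, j], paired = TRUE)$p.value
        else if (all(d == 0)) 1 else 0
        pmat[i, j] <- pmat[j, i] <- p
        pw[[length(pw) + 1]] <-
          data.frame(model = model, scheme_a = schemes[i],
                     scheme_b = schemes[j],
                     delta_accuracy = mean(d), p_value = p)
      }
    }
    letters_ <- cld_letters(colMeans(acc), pmat, alpha)
    tabs[[model]] <- data.frame(
      model = model, scheme = schemes,
      accuracy_mean = colMeans(acc), accuracy_sd = apply(acc, 2, sd),
      unbiasedness_mean = colMeans(bias), unbiasedness_sd = apply(bias, 2, sd),
      letters = letters_[schemes], row.names = NULL)
  }
  structure(list(table = do.call(rbind, tabs),
                 pairwise = do.call(rbind, pw),
                 n_replicates = length(unique(agg$replicate))),
            class = "cv_summary")
}

## compact letter display: schemes in decreasing mean order; a scheme
## joins an existing letter group iff it is not significantly different
## from every member, otherwise it opens a new letter
cld_letters <- function(means, pmat, alpha = 0.05) {
  ord <- names(sort(means, decreasing = TRUE))
  groups <- list()
  lab <- setNames(rep("", length(ord)), ord)
  for (s in ord) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(pmat[s, groups[[gi]]] >= alpha)) {
        groups[[gi]] <- c(groups[[gi]], s)
        lab[s] <- paste0(lab[s], letters[gi])
        placed <- TRUE
      }
    }
    if (!placed) {
      groups[[length(groups) + 1]] <- s
      lab[s] <- paste0(lab[s], letters[length(groups)])
    }
  }
  lab
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("cross-validation summary over", x$n_replicates, "replicates\n")
  t <- x$table
  t$accuracy <- sprintf("%.3f +/- %.3f%s", t$accuracy_mean, t$accuracy_sd,
                        t$letters)
  t$unbiasedness <- sprintf("%.3f +/- %.3f", t$unbiasedness_mean,
                            t$unbiasedness_sd)
  print(t[, c("model", "scheme", "accuracy", "unbiasedness")],
        row.names = FALSE)
  invisible(x)
}
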