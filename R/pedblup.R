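## Conventional pedigree-based evaluation: Henderson's mixed-model
## equations for the animal model (growth traits: herd/year/season/sex
## fixed, animal + common litter random) and the repeatability model
## (reproduction traits: herd/year/season fixed, animal + permanent
## environment random), REML variance components, and corrected
## phenotypes y_c = EBV + (mean) estimated residual.

#' Specify a pedigree mixed model
#'
#' @param trait trait name (matched against the phenotype table)
#' @param type `"growth"` (single record, litter effect, sex in the fixed
#'   part) or `"repro"` (repeated records, permanent-environment effect)
#' @param fixed_terms character vector of fixed-effect columns
#' @param random_terms character subset of `c("animal", "litter",
#'   "permanent_environment")`
#' @return a `ped_model` specification.
#' @export
ped_model <- function(trait, type = c("growth", "repro"),
                      fixed_terms = NULL, random_terms = NULL) {
  type <- match.arg(type)
  if (is.null(fixed_terms))
    fixed_terms <- if (type == "growth") c("herd", "year", "season", "sex")
                   else c("herd", "year", "season")
  if (is.null(random_terms))
    random_terms <- if (type == "growth") c("animal", "litter")
                    else c("animal", "permanent_environment")
  repeated <- type == "repro"
  if (repeated && !("permanent_environment" %in% random_terms))
    stop("a repeated-records model requires the permanent_environment term")
  structure(list(trait = trait, type = type, fixed_terms = fixed_terms,
                 random_terms = random_terms, repeated = repeated),
            class = "ped_model")
}

## Assemble the design pieces shared by solve_mme() and reml_estimate().
mme_design <- function(model, pheno, ped) {
  rec <- pheno[pheno$trait == model$trait, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for trait ", model$trait)
  miss <- setdiff(unique(rec$id), ped$id)
  if (length(miss) > 0)
    stop("record id(s) not in pedigree: ", paste(head(miss, 3), collapse = ", "))
  for (f in model$fixed_terms)
    if (!f %in% names(rec)) stop("fixed term absent from phenotypes: ", f)
  ## single-level factors are absorbed by the intercept
  active <- model$fixed_terms[vapply(model$fixed_terms, function(f)
    length(unique(rec[[f]])) > 1, logical(1))]
  fml <- if (length(active) == 0) ~1 else
    stats::as.formula(paste("~", paste(sprintf("factor(%s)", active),
                                       collapse = " + ")))
  X <- model.matrix(fml, data = rec)
  ## rank-deficiency: treatment contrasts constrain the first level of each
  ## factor to zero; drop any remaining aliased columns
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  n <- nrow(rec)
  an <- match(rec$id, ped$id)
  Za <- sparseMatrix(i = seq_len(n), j = an, x = 1,
                     dims = c(n, length(ped$id)))
  Zlist <- list(animal = Za)
  if ("litter" %in% model$random_terms) {
    lit <- factor(rec$litter)
    Zlist$litter <- sparseMatrix(i = seq_len(n), j = as.integer(lit), x = 1,
                                 dims = c(n, nlevels(lit)))
  }
  if ("permanent_environment" %in% model$random_terms) {
    pe <- factor(rec$id)
    Zlist$permanent_environment <-
      sparseMatrix(i = seq_len(n), j = as.integer(pe), x = 1,
                   dims = c(n, nlevels(pe)))
    pe_ids <- levels(pe)
  } else pe_ids <- NULL
  list(rec = rec, X = Matrix(X, sparse = TRUE), Zlist = Zlist,
       aliased = aliased, pe_ids = pe_ids, n = n)
}

vc_sigma <- function(vc, term) {
  key <- c(animal = "sigma2_a", litter = "sigma2_litter",
           permanent_environment = "sigma2_pe")[[term]]
  v <- vc[[key]]
  if (is.null(v) || is.na(v)) stop("variance component missing: ", key)
  v
}

#' Solve Henderson's mixed-model equations
#'
#' Animal effects carry the pedigree covariance (`A sigma2_a` via the
#' sparse A-inverse); litter and permanent-environment effects are iid.
#' Residuals are `record - fixed - all fitted random terms`; prediction
#' error variances come from the inverse coefficient matrix.
#'
#' @param model a [ped_model]
#' @param pheno phenotype data.frame (columns id, trait, value plus the
#'   model's fixed terms, `litter`, `parity`)
#' @param ped a [pedigree] covering every record id
#' @param vc list of variance components: `sigma2_a`, `sigma2_e` and, as
#'   required by the model, `sigma2_litter` / `sigma2_pe`
#' @param compute_pev logical; invert the coefficient matrix for PEV and
#'   reliability (dense inverse; skip for very large systems)
#' @return a `pedblup_fit`: list with `ebv` (named, all pedigree
#'   individuals), `pev`, `reliability`, `fixef`, `residuals` (per
#'   record), `records` and the model/vc used.
#' @export
solve_mme <- function(model, pheno, ped, vc, compute_pev = TRUE) {
  if (!is.finite(vc$sigma2_e) || vc$sigma2_e <= 0)
    stop("residual variance must be strictly positive")
  des <- mme_design(model, pheno, ped)
  ainv <- a_inverse(ped)
  W <- cbind(des$X, do.call(cbind, des$Zlist))
  p <- ncol(des$X)
  q <- vapply(des$Zlist, ncol, integer(1))
  Ginv_blocks <- list(Diagonal(p, 0))
  for (term in names(des$Zlist)) {
    Ginv_blocks[[term]] <- if (term == "animal") ainv$Ainv / vc_sigma(vc, term)
                           else Diagonal(q[[term]]) / vc_sigma(vc, term)
  }
  C <- crossprod(W) / vc$sigma2_e + forceSymmetric(bdiag(Ginv_blocks))
  rhs <- crossprod(W, des$rec$value) / vc$sigma2_e
  sol <- as.numeric(solve(C, rhs))
  b <- sol[seq_len(p)]
  off <- p
  u <- list()
  for (term in names(des$Zlist)) {
    u[[term]] <- sol[off + seq_len(q[[term]])]
    off <- off + q[[term]]
  }
  names(u$animal) <- ped$id
  fitted <- as.numeric(W %*% sol)
  resid <- des$rec$value - fitted
  pev <- rel <- setNames(rep(NA_real_, length(ped$id)), ped$id)
  if (compute_pev && ncol(C) <= 8000) {
    Cinv_diag <- diag(solve(as(C, "generalMatrix")))
    pev <- setNames(Cinv_diag[p + seq_len(q[["animal"]])], ped$id)
    rel <- pmin(pmax(1 - pev / vc$sigma2_a, 0), 1)
  }
  structure(list(ebv = u$animal, u = u, pev = pev, reliability = rel,
                 fixef = setNames(b, colnames(des$X)),
                 residuals = resid, records = des$rec,
                 aliased = des$aliased, model = model, vc = vc),
            class = "pedblup_fit")
}

#' @export
print.pedblup_fit <- function(x, ...) {
  cat("pedigree BLUP fit:", x$model$trait, sprintf("(%s model), ", x$model$type),
      length(x$ebv), "animals,", length(x$residuals), "records\n")
  invisible(x)
}

## REML log-likelihood via the MME identity
##   -2 l_R = N log s2e + sum_k [ q_k log s2k + log|K_k| ] + log|C| + y'Py
## with y'Py = (y'y - sol' W'y) / s2e.  Verified against the dense
## (V, X'V^-1X) form in the test suite.
reml_m2ll <- function(theta, pre) {
  s2e <- theta[["residual"]]
  C <- pre$WtW / s2e
  ld_g <- 0
  for (term in pre$terms) {
    C <- C + pre$pattern[[term]] / theta[[term]]
    ld_g <- ld_g + pre$q[[term]] * log(theta[[term]]) +
      if (term == "animal") pre$logdet_A else 0
  }
  C <- forceSymmetric(C)
  ch <- tryCatch(Matrix::Cholesky(C, LDL = TRUE, super = FALSE),
                 error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ld_C <- 2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  sol <- as.numeric(solve(ch, pre$Wty / s2e))
  ypy <- (pre$yty - sum(sol * pre$Wty)) / s2e
  pre$n * log(s2e) + ld_g + ld_C + ypy
}

#' REML variance components for a pedigree mixed model
#'
#' Maximizes the restricted likelihood directly (quasi-Newton on
#' log-variances, using the sparse mixed-model-equation form of the
#' likelihood).  Standard errors come from the inverse numerical REML
#' information matrix; the heritability SE uses the delta method.
#'
#' @param model a [ped_model]
#' @param pheno phenotype data.frame
#' @param ped a [pedigree]
#' @param init optional named list of starting values (`sigma2_a`, ...)
#' @param max_iter iteration cap passed to the optimizer
#' @return a `vc_estimate`: list with `components` (data.frame term,
#'   sigma2, se), `h2`, `h2_se`, `repeatability` (repeated models),
#'   `logLik`, `converged`.
#' @export
reml_estimate <- function(model, pheno, ped, init = NULL, max_iter = 200) {
  des <- mme_design(model, pheno, ped)
  ainv <- a_inverse(ped)
  W <- cbind(des$X, do.call(cbind, des$Zlist))
  p <- ncol(des$X)
  q <- lapply(des$Zlist, ncol)
  terms <- names(des$Zlist)
  nW <- ncol(W)
  pattern <- list()
  off <- p
  for (term in terms) {
    qi <- q[[term]]
    blk <- if (term == "animal") ainv$Ainv else Diagonal(qi)
    pattern[[term]] <- bdiag(Diagonal(off, 0), blk, Diagonal(nW - off - qi, 0))
    off <- off + qi
  }
  y <- des$rec$value
  pre <- list(WtW = crossprod(W), Wty = as.numeric(crossprod(W, y)),
              yty = sum(y^2), n = des$n, q = q, terms = terms,
              pattern = pattern, logdet_A = ainv$logdet_A)
  vy <- var(y)
  th0 <- c(setNames(rep(0.2 * vy, length(terms)), terms), residual = 0.6 * vy)
  if (!is.null(init)) {
    key <- c(animal = "sigma2_a", litter = "sigma2_litter",
             permanent_environment = "sigma2_pe", residual = "sigma2_e")
    for (nm in names(th0))
      if (!is.null(init[[key[[nm]]]])) th0[[nm]] <- init[[key[[nm]]]]
  }
  fn <- function(lp) reml_m2ll(setNames(exp(lp), names(th0)), pre)
  opt <- optim(log(th0), fn, method = "Nelder-Mead",
               control = list(maxit = max_iter * 10, reltol = 1e-12))
  theta <- exp(opt$par)
  ## SEs from the numerical REML information (0.5 * Hessian of -2 l_R on
  ## the variance scale)
  H <- tryCatch(optimHess(theta, function(th) {
    th <- pmax(th, 1e-12 * vy)
    0.5 * reml_m2ll(setNames(th, names(th0)), pre)
  }), error = function(e) NULL)
  se <- rep(NA_real_, length(theta))
  vcov <- NULL
  if (!is.null(H)) {
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov)) se <- sqrt(pmax(diag(vcov), 0))
  }
  tot <- sum(theta)
  h2 <- theta[["animal"]] / tot
  h2_se <- NA_real_
  if (!is.null(vcov)) {
    g <- rep(-h2 / tot, length(theta))
    g[match("animal", names(th0))] <- (tot - theta[["animal"]]) / tot^2
    h2_se <- sqrt(max(0, as.numeric(t(g) %*% vcov %*% g)))
  }
  repeatability <- if (model$repeated)
    (theta[["animal"]] + theta[["permanent_environment"]]) / tot else NA_real_
  key <- c(animal = "sigma2_a", litter = "sigma2_litter",
           permanent_environment = "sigma2_pe", residual = "sigma2_e")
  vc <- as.list(setNames(theta, key[names(theta)]))
  structure(list(components = data.frame(term = names(theta),
                                         sigma2 = unname(theta),
                                         se = unname(se)),
                 vc = vc, h2 = unname(h2), h2_se = unname(h2_se),
                 repeatability = unname(repeatability),
                 logLik = -0.5 * opt$value, converged = opt$convergence == 0),
            class = "vc_estimate")
}

#' @export
print.vc_estimate <- function(x, ...) {
  print(x$components)
  cat(sprintf("h2 = %.3f (SE %.3f)", x$h2, x$h2_se))
  if (!is.na(x$repeatability))
    cat(sprintf(", repeatability = %.3f", x$repeatability))
  cat("\n")
  invisible(x)
}

#' Corrected phenotypes from a pedigree BLUP fit
#'
#' Growth traits: `y_c = EBV + estimated residual` (one record per
#' animal).  Reproduction traits: `y_c = EBV + mean of the estimated
#' residuals over the sow's parities`.  Animals without records are
#' excluded and listed.
#'
#' @param fit a [solve_mme] result
#' @return data.frame with columns `id`, `yc`, `n_records`; the excluded
#'   (record-less) ids are attached as `attr(, "excluded")`.
#' @export
corrected_phenotypes <- function(fit) {
  rid <- fit$records$id
  mean_res <- tapply(fit$residuals, rid, mean)
  cnt <- tapply(fit$residuals, rid, length)
  ids <- names(mean_res)
  out <- data.frame(id = ids,
                    yc = unname(fit$ebv[ids] + mean_res),
                    n_records = as.integer(cnt))
  attr(out, "excluded") <- setdiff(names(fit$ebv), ids)
  rownames(out) <- NULL
  out
}
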