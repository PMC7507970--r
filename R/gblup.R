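## Genomic BLUP.  Single-trait: y = 1 mu + Z a + e with a ~ N(0, G s2a),
## variance components by REML on the eigendecomposition of the reference
## GRM (exact, one-dimensional profile likelihood in the variance ratio).
## Multi-trait (environment-as-trait): y stacks the two populations'
## corrected phenotypes, g ~ N(0, G (x) M), e ~ N(0, I (x) R) with R
## diagonal (no individual is recorded in both environments, so the
## residual covariance never enters the likelihood); M and R by AI-REML
## with step-halving and PSD bending as safeguards.

#' Single-trait GBLUP: fit on a reference set, predict all individuals
#'
#' @param grm a [make_grm] result covering reference and validation
#'   animals
#' @param y named numeric vector of corrected phenotypes for the
#'   *reference* animals only (validation phenotypes must be withheld by
#'   the caller)
#' @param vc optional list with `sigma2_a` and `sigma2_e`; when NULL both
#'   are REML-estimated on the reference set
#' @param stabilize ridge added to the GRM diagonal
#' @return a `st_gblup_fit`: list with `gebv` (named, every individual in
#'   the GRM), `mu`, `vc` (list: sigma2_a, sigma2_e, h2) and `logLik`.
#' @export
st_gblup <- function(grm, y, vc = NULL, stabilize = 1e-6) {
  ids <- grm$ids
  if (is.null(names(y))) stop("y must be named by individual id")
  ref <- match(names(y), ids)
  if (anyNA(ref)) stop("reference id(s) missing from the GRM")
  g <- grm$matrix + diag(stabilize, length(ids))
  gr <- g[ref, ref]
  e <- eigen(gr, symmetric = TRUE)
  d <- pmax(e$values, 0)
  ystar <- as.numeric(crossprod(e$vectors, y))
  xstar <- as.numeric(crossprod(e$vectors, rep(1, length(y))))
  n <- length(y)
  prof <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * d + 1
    sxx <- sum(xstar^2 / w)
    beta <- sum(xstar * ystar / w) / sxx
    r <- ystar - xstar * beta
    s2e <- sum(r^2 / w) / (n - 1)
    list(m2ll = sum(log(w)) + log(sxx) + (n - 1) * log(s2e),
         beta = beta, s2e = s2e)
  }
  if (is.null(vc)) {
    opt <- optimize(function(l) prof(l)$m2ll, c(-12, 12), tol = 1e-9)
    pr <- prof(opt$minimum)
    s2e <- pr$s2e
    s2a <- exp(opt$minimum) * s2e
    m2ll <- pr$m2ll
  } else {
    s2a <- vc$sigma2_a; s2e <- vc$sigma2_e
    pr <- prof(log(s2a / s2e))
    m2ll <- NA_real_
  }
  w_inv <- 1 / (s2a * d + s2e)
  resid_rot <- ystar - xstar * pr$beta
  vinv_e <- e$vectors %*% (w_inv * resid_rot)   # V^-1 (y - 1 mu)
  gebv <- as.numeric(s2a * g[, ref] %*% vinv_e)
  names(gebv) <- ids
  structure(list(gebv = gebv, mu = pr$beta,
                 vc = list(sigma2_a = s2a, sigma2_e = s2e,
                           h2 = s2a / (s2a + s2e)),
                 logLik = -0.5 * m2ll, n_ref = n),
            class = "st_gblup_fit")
}

#' @export
print.st_gblup_fit <- function(x, ...) {
  cat(sprintf("ST-GBLUP fit: n_ref = %d, h2 = %.3f, mu = %.3f\n",
              x$n_ref, x$vc$h2, x$mu))
  invisible(x)
}

## eigenvalue floor at 1e-6 of the trace keeps the 2x2 genetic matrix PSD
bend_psd <- function(m, floor_frac = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lo <- floor_frac * max(sum(pmax(e$values, 0)), 1e-12)
  if (all(e$values >= lo)) return(list(m = m, bent = FALSE))
  v <- pmax(e$values, lo)
  list(m = e$vectors %*% (v * t(e$vectors)), bent = TRUE)
}

#' Multi-trait (environment-as-trait) GBLUP
#'
#' Treats the same trait measured in the two populations as two
#' correlated traits.  Each individual carries a record for exactly one
#' environment-trait; the joint GRM must span both populations.  When
#' variance components are not supplied they are estimated by AI-REML
#' (average information, with step-halving and PSD bending safeguards,
#' convergence at relative parameter change < 1e-8, cap 200 iterations).
#'
#' @param grm joint [make_grm] result over both populations
#' @param y1 named corrected phenotypes of environment-1 (population-1)
#'   reference animals
#' @param y2 named corrected phenotypes of environment-2 reference animals
#' @param vc optional list with `M` (2x2 genetic covariance) and `R`
#'   (length-2 residual variances); skips REML
#' @param stabilize ridge added to the GRM diagonal
#' @param init optional starting values `c(g11, g12, g22, e1, e2)`
#' @return an `mt_gblup_fit`: list with `gebv1`, `gebv2` (named, every
#'   individual in the GRM, GEBV on the trait-1 / trait-2 scale), `mu`
#'   (length 2), `cc` (a `cov_components`: M, R, rg, se_rg), `niter`,
#'   `converged`.
#' @export
mt_gblup <- function(grm, y1, y2, vc = NULL, stabilize = 1e-6, init = NULL,
                     max_iter = 200, tol = 1e-8) {
  ids <- grm$ids
  if (length(intersect(names(y1), names(y2))) > 0)
    stop("an individual cannot be phenotyped in both environments")
  ref <- match(c(names(y1), names(y2)), ids)
  if (anyNA(ref)) stop("reference id(s) missing from the GRM")
  g <- grm$matrix + diag(stabilize, length(ids))
  gr <- g[ref, ref]
  tr <- rep(1:2, c(length(y1), length(y2)))
  y <- c(y1, y2)
  n <- length(y)
  X <- cbind(as.numeric(tr == 1), as.numeric(tr == 2))
  m11 <- outer(tr == 1, tr == 1); m22 <- outer(tr == 2, tr == 2)
  m12 <- outer(tr == 1, tr == 2); m12 <- m12 | t(m12)
  build_V <- function(th) {
    ## elementwise M[t_i, t_j] via column-major index trick
    Mbig <- matrix(c(th[1], th[2], th[2], th[3]), 2)[cbind(rep(tr, n), rep(tr, each = n))]
    dim(Mbig) <- c(n, n)
    gr * Mbig + diag(c(th[4], th[5])[tr])
  }
  m2ll_of <- function(th) {
    V <- build_V(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    Vinv <- chol2inv(ch)
    XtVX <- crossprod(X, Vinv %*% X)
    Py <- Vinv %*% y - Vinv %*% X %*% solve(XtVX, crossprod(X, Vinv %*% y))
    2 * sum(log(diag(ch))) + as.numeric(determinant(XtVX)$modulus) +
      sum(y * Py)
  }
  if (is.null(vc)) {
    v1 <- var(y1); v2 <- var(y2)
    th <- if (is.null(init)) c(0.5 * v1, 0.25 * sqrt(v1 * v2), 0.5 * v2,
                               0.5 * v1, 0.5 * v2) else init
    ll_old <- m2ll_of(th)
    converged <- FALSE
    iter <- 0
    n_stall <- 0
    vcov_th <- NULL
    while (iter < max_iter) {
      iter <- iter + 1
      V <- build_V(th)
      Vinv <- chol2inv(chol(V))
      VinvX <- Vinv %*% X
      XtVX_inv <- solve(crossprod(X, VinvX))
      P <- Vinv - VinvX %*% XtVX_inv %*% t(VinvX)
      Py <- as.numeric(P %*% y)
      Vk_list <- list(gr * m11, gr * m12, gr * m22,
                      diag(as.numeric(tr == 1)), diag(as.numeric(tr == 2)))
      VkPy <- lapply(Vk_list, function(Vk) as.numeric(Vk %*% Py))
      PVkPy <- lapply(VkPy, function(v) as.numeric(P %*% v))
      score <- vapply(seq_along(Vk_list), function(k)
        -0.5 * (sum(P * Vk_list[[k]]) - sum(Py * VkPy[[k]])), numeric(1))
      AI <- matrix(0, 5, 5)
      for (k in 1:5) for (l in k:5) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(VkPy[[k]] * PVkPy[[l]])
      }
      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (is.null(delta)) delta <- score / pmax(diag(AI), 1e-8)
      step <- 1
      repeat {
        th_new <- th + step * delta
        Mn <- matrix(c(th_new[1], th_new[2], th_new[2], th_new[3]), 2)
        bm <- bend_psd(Mn)
        th_new[1] <- bm$m[1, 1]; th_new[2] <- bm$m[1, 2]; th_new[3] <- bm$m[2, 2]
        th_new[4:5] <- pmax(th_new[4:5], 1e-8 * c(v1, v2))
        ll_new <- m2ll_of(th_new)
        if (is.finite(ll_new) && ll_new <= ll_old + 1e-8) break
        step <- step / 2
        if (step < 1e-2) { th_new <- th; ll_new <- ll_old; break }
      }
      rel <- max(abs(th_new - th) / (abs(th) + 1e-8))
      th <- th_new
      ## stall detection: repeated bent/halved steps at a likelihood
      ## plateau (typically the PSD boundary, rg -> 1) count as converged
      n_stall <- if (abs(ll_old - ll_new) < 1e-7 * (abs(ll_old) + 1))
        n_stall + 1 else 0
      if (rel < tol || abs(ll_old - ll_new) < 1e-12 || n_stall >= 3) {
        converged <- TRUE
        ll_old <- ll_new
        vcov_th <- tryCatch(solve(AI), error = function(e) NULL)
        break
      }
      ll_old <- ll_new
      if (iter == max_iter) vcov_th <- tryCatch(solve(AI), error = function(e) NULL)
    }
    M <- matrix(c(th[1], th[2], th[2], th[3]), 2)
    R <- th[4:5]
  } else {
    M <- vc$M; R <- vc$R
    th <- c(M[1, 1], M[1, 2], M[2, 2], R[1], R[2])
    converged <- TRUE; iter <- 0
    vcov_th <- vc$vcov_th %||% NULL
  }
  psd_check <- bend_psd(M)
  if (psd_check$bent) M <- psd_check$m
  if (any(eigen(M, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("genetic covariance matrix not PSD after bending")
  rg <- M[1, 2] / sqrt(M[1, 1] * M[2, 2])
  se_rg <- NA_real_
  if (!is.null(vcov_th)) {
    gvec <- c(-0.5 * rg / M[1, 1], 1 / sqrt(M[1, 1] * M[2, 2]),
              -0.5 * rg / M[2, 2], 0, 0)
    se_rg <- sqrt(max(0, as.numeric(t(gvec) %*% vcov_th %*% gvec)))
  }
  ## BLUE and BLUP at the final components
  V <- gr * matrix(M[cbind(rep(tr, n), rep(tr, each = n))], n, n) +
    diag(R[tr])
  Vinv <- chol2inv(chol(V))
  XtVX <- crossprod(X, Vinv %*% X)
  mu <- as.numeric(solve(XtVX, crossprod(X, Vinv %*% y)))
  w <- as.numeric(Vinv %*% (y - X %*% mu))
  gebv1 <- as.numeric(g[, ref] %*% (M[1, tr] * w)); names(gebv1) <- ids
  gebv2 <- as.numeric(g[, ref] %*% (M[2, tr] * w)); names(gebv2) <- ids
  cc <- structure(list(M = M, R = R, rg = rg, se_rg = se_rg,
                       bent = psd_check$bent),
                  class = "cov_components")
  structure(list(gebv1 = gebv1, gebv2 = gebv2, mu = setNames(mu, c("env1", "env2")),
                 cc = cc, niter = iter, converged = converged),
            class = "mt_gblup_fit")
}

#' @export
print.mt_gblup_fit <- function(x, ...) {
  cat(sprintf("MT-GBLUP fit: rg = %.3f (SE %.3f), %d AI-REML iterations%s\n",
              x$cc$rg, x$cc$se_rg, x$niter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
print.cov_components <- function(x, ...) {
  cat("genetic (co)variances: g11 =", signif(x$M[1, 1], 4),
      " g12 =", signif(x$M[1, 2], 4), " g22 =", signif(x$M[2, 2], 4), "\n")
  cat("residual variances:", signif(x$R[1], 4), signif(x$R[2], 4), "\n")
  cat(sprintf("rg = %.3f (SE %.3f)\n", x$rg, x$se_rg))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag a genotype-by-environment interaction
#'
#' A between-environment genetic correlation strictly below the threshold
#' (0.8 by Robertson's rule of biological importance) flags a G x E
#' interaction.
#'
#' @param cc a `cov_components` (from [mt_gblup]) or a list with `rg` and
#'   optionally `se_rg`
#' @param threshold flagging threshold (default 0.8; strict `<`)
#' @return a `gxe_assessment`: list with `rg`, `se_rg`, `threshold`,
#'   `flagged`.
#' @export
assess_gxe <- function(cc, threshold = 0.8) {
  if (is.null(cc$rg) || is.na(cc$rg)) stop("rg has not been estimated")
  structure(list(rg = cc$rg, se_rg = cc$se_rg %||% NA_real_,
                 threshold = threshold, flagged = cc$rg < threshold),
            class = "gxe_assessment")
}

#' @export
print.gxe_assessment <- function(x, ...) {
  cat(sprintf("rg = %.3f (SE %s); threshold %.2f -> %s\n", x$rg,
              ifelse(is.na(x$se_rg), "NA", sprintf("%.3f", x$se_rg)),
              x$threshold,
              if (x$flagged) "G x E interaction flagged" else "no G x E flag"))
  invisible(x)
}
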