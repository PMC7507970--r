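test_that("A-inverse matches the dense tabular inverse", {
  ## trio oracle: unrelated sire + dam with one offspring
  trio <- pedigree(data.frame(id = c("s", "d", "o"), sire = c("0", "0", "s"),
                              dam = c("0", "0", "d")))
  expect_equal(unname(a_matrix(trio)),
               matrix(c(1, 0, 0.5, 0, 1, 0.5, 0.5, 0.5, 1), 3))
  ai <- a_inverse(trio)
  expect_equal(unname(as.matrix(ai$Ainv)),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3))
  ## founders only: identity
  f <- pedigree(data.frame(id = c("a", "b"), sire = 0, dam = 0))
  expect_equal(unname(as.matrix(a_inverse(f)$Ainv)), diag(2))
  ## random pedigrees up to 200 individuals, with inbreeding
  for (seed in 1:4) {
    n <- sample(50:200, 1)
    ped <- pedigree(random_pedigree(n, seed = seed))
    A <- a_matrix(ped)
    ai <- a_inverse(ped)
    expect_lt(max(abs(as.matrix(ai$Ainv) - solve(A))), 1e-8)
    expect_equal(ai$logdet_A, as.numeric(determinant(A)$modulus),
                 tolerance = 1e-8)
    expect_equal(unname(ai$f), unname(diag(A)) - 1, tolerance = 1e-12)
  }
})

test_that("pedigree validation orders parents first and detects cycles", {
  ## offspring listed before parent: reordered, not rejected
  ped <- pedigree(data.frame(id = c("kid", "pa", "ma"),
                             sire = c("pa", "0", "0"),
                             dam = c("ma", "0", "0")))
  expect_equal(ped$id[3], "kid")
  expect_error(pedigree(data.frame(id = c("x", "y"), sire = c("y", "x"),
                                   dam = c("0", "0"))),
               "cycle")
  expect_error(pedigree(data.frame(id = "x", sire = "ghost", dam = "0")),
               "not in pedigree")
})

test_that("MME solutions equal the dense GLS/BLUP oracle", {
  set.seed(14)
  ped <- pedigree(random_pedigree(20, n_founders = 6, seed = 14))
  ids <- ped$id[7:20]
  ph <- data.frame(id = rep(ids, each = 2), trait = "T",
                   value = rnorm(28, 10, 2),
                   herd = sample(1:2, 28, TRUE), year = sample(1:3, 28, TRUE),
                   season = 1, sex = 0, litter = NA,
                   parity = rep(1:2, 14))
  m <- ped_model("T", "repro")
  vc <- list(sigma2_a = 1.3, sigma2_pe = 0.6, sigma2_e = 2.1)
  fit <- solve_mme(m, ph, ped, vc)
  ## dense oracle: GLS fixed effects, BLUP u = G Z' V^-1 (y - X b)
  X <- stats::model.matrix(~ factor(herd) + factor(year), ph)
  A <- a_matrix(ped)
  Za <- outer(ph$id, ped$id, "==") * 1
  Zp <- outer(ph$id, unique(ph$id), "==") * 1
  V <- vc$sigma2_a * Za %*% A %*% t(Za) + vc$sigma2_pe * tcrossprod(Zp) +
    vc$sigma2_e * diag(nrow(ph))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% ph$value)
  u <- vc$sigma2_a * A %*% t(Za) %*% Vi %*% (ph$value - X %*% b)
  expect_lt(max(abs(fit$ebv - as.numeric(u))), 1e-8)
  expect_lt(max(abs(unname(fit$fixef) - as.numeric(b))), 1e-8)
  ## PEV from the dense coefficient-matrix inverse
  expect_true(all(fit$reliability >= 0 & fit$reliability <= 1))
  ## reliability grows with record count
  one_rec <- ph[!duplicated(ph$id), ]
  fit1 <- solve_mme(m, one_rec, ped, vc)
  expect_true(all(fit$reliability[ids] > fit1$reliability[ids]))
})

test_that("MME limits behave as ridge theory predicts", {
  set.seed(15)
  ped <- pedigree(random_pedigree(15, n_founders = 5, seed = 15))
  ph <- data.frame(id = ped$id[6:15], trait = "T", value = rnorm(10, 3),
                   herd = 1, year = 1, season = 1, sex = 0,
                   litter = paste0("L", 1:10), parity = NA)
  m <- ped_model("T", "growth")
  ## sigma2_a -> 0: EBVs vanish, the mean is the GLS fit, residuals centered
  fit0 <- solve_mme(m, ph, ped, list(sigma2_a = 1e-10, sigma2_litter = 1e-10,
                                     sigma2_e = 1), compute_pev = FALSE)
  expect_lt(max(abs(fit0$ebv)), 1e-6)
  expect_equal(unname(fit0$fixef[1]), mean(ph$value), tolerance = 1e-6)
  expect_equal(sum(fit0$residuals), 0, tolerance = 1e-6)
})

test_that("REML likelihood equals the dense (V, X'V^-1 X) form", {
  set.seed(16)
  ped <- pedigree(random_pedigree(12, n_founders = 4, seed = 16))
  ph <- data.frame(id = rep(ped$id[5:12], each = 2), trait = "T",
                   value = rnorm(16, 10), herd = sample(1:2, 16, TRUE),
                   year = sample(1:2, 16, TRUE), season = 1, sex = 0,
                   litter = NA, parity = rep(1:2, 8))
  m <- ped_model("T", "repro")
  des <- gxepred:::mme_design(m, ph, ped)
  ainv <- a_inverse(ped)
  W <- cbind(des$X, do.call(cbind, des$Zlist))
  p <- ncol(des$X); q <- lapply(des$Zlist, ncol); nW <- ncol(W)
  pattern <- list(); off <- p
  for (term in names(des$Zlist)) {
    qi <- q[[term]]
    blk <- if (term == "animal") ainv$Ainv else Matrix::Diagonal(qi)
    pattern[[term]] <- Matrix::bdiag(Matrix::Diagonal(off, x = 0), blk,
                                     Matrix::Diagonal(nW - off - qi, x = 0))
    off <- off + qi
  }
  y <- des$rec$value
  pre <- list(WtW = Matrix::crossprod(W), Wty = as.numeric(Matrix::crossprod(W, y)),
              yty = sum(y^2), n = des$n, q = q, terms = names(des$Zlist),
              pattern = pattern, logdet_A = ainv$logdet_A)
  A <- a_matrix(ped)
  X <- as.matrix(des$X)
  Za <- as.matrix(des$Zlist$animal)
  Zp <- as.matrix(des$Zlist$permanent_environment)
  dense <- function(th) {
    V <- th[1] * Za %*% A %*% t(Za) + th[2] * tcrossprod(Zp) +
      th[3] * diag(length(y))
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
    as.numeric(determinant(V)$modulus + determinant(XtVX)$modulus +
                 t(y) %*% P %*% y)
  }
  for (th in list(c(1, 0.5, 2), c(0.3, 0.2, 1), c(2, 1, 0.5))) {
    mme <- gxepred:::reml_m2ll(
      c(animal = th[1], permanent_environment = th[2], residual = th[3]), pre)
    expect_equal(mme, dense(th), tolerance = 1e-8)
  }
})

test_that("REML recovers simulated variance ratios", {
  sim <- small_gxe_sim()
  ped <- pedigree(sim$ped1)
  est <- reml_estimate(ped_model("GT", "growth"),
                       sim$pheno[sim$pheno$pop == "pop1", ], ped)
  expect_true(est$converged)
  expect_lt(abs(est$h2 - 0.35), 0.15)            # small-n unit check
  expect_gt(est$h2_se, 0)
  expect_true(all(est$components$sigma2 >= 0))
})

test_that("corrected phenotypes follow the EBV-plus-residual rule", {
  ## forced arithmetic: EBV 1.0, residuals (0.2, 0.4) -> y_c = 1.3
  fit <- structure(list(ebv = c(a = 1.0, b = 2.0, c = 0.5),
                        residuals = c(0.2, 0.4, -0.1),
                        records = data.frame(id = c("a", "a", "b"))),
                   class = "pedblup_fit")
  yc <- corrected_phenotypes(fit)
  expect_equal(yc$yc[yc$id == "a"], 1.3)
  ## single record: identical to the growth formula
  expect_equal(yc$yc[yc$id == "b"], 2.0 - 0.1)
  ## record-less animals are excluded and listed
  expect_equal(attr(yc, "excluded"), "c")
  ## all residuals zero: y_c = EBV
  fit$residuals <- rep(0, 3)
  expect_equal(corrected_phenotypes(fit)$yc, unname(fit$ebv[c("a", "b")]))
})
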