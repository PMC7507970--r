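test_that("fold partitions obey the remainder rule and partition laws", {
  ids10 <- paste0("a", 1:10)
  f <- make_folds(ids10, k = 5, seed = 1)
  expect_equal(as.integer(sort(table(f))), rep(2L, 5))
  ids11 <- paste0("b", 1:11)
  f11 <- make_folds(ids11, k = 5, seed = 1)
  expect_equal(as.integer(sort(table(f11), decreasing = TRUE)),
               c(3L, 2L, 2L, 2L, 2L))
  ## exhaustive, disjoint, deterministic
  expect_setequal(names(f11), ids11)
  expect_identical(f11, make_folds(ids11, k = 5, seed = 1))
  expect_false(identical(f11, make_folds(ids11, k = 5, seed = 2)))
  expect_error(make_folds(ids10, k = 1), "at least 2")
  expect_error(make_folds(ids10[1:3], k = 5), "fewer ids")
})

test_that("accuracy and unbiasedness follow their definitions", {
  set.seed(71)
  yc <- setNames(rnorm(50), paste0("v", 1:50))
  ## identity: r = 1, b = 1
  ab <- accuracy_and_bias(yc, yc)
  expect_equal(ab$r, 1); expect_equal(ab$b, 1)
  ## halving the GEBV leaves r and doubles b (scale law)
  ab2 <- accuracy_and_bias(yc, 0.5 * yc)
  expect_equal(ab2$r, 1); expect_equal(ab2$b, 2)
  ## zero GEBV variance: flagged undefined, not an error
  ab0 <- accuracy_and_bias(yc, yc * 0)
  expect_false(ab0$defined)
  expect_true(is.na(ab0$r))
  expect_error(accuracy_and_bias(yc[1:2], yc[1:2]), "at least 3")
  ## names are honored
  ab3 <- accuracy_and_bias(yc, rev(yc))
  expect_equal(ab3$r, 1)
})

test_that("permuted GEBVs have null accuracy", {
  set.seed(72)
  yc <- rnorm(500)
  hits <- sum(replicate(100, abs(cor(yc, sample(yc))) < 0.1))
  expect_gte(hits, 95)
})

test_that("scheme references exclude the validation fold everywhere", {
  yt <- setNames(rnorm(20), paste0("t", 1:20))
  yo <- setNames(rnorm(10), paste0("o", 1:10))
  val <- names(yt)[1:4]
  for (s in c("st_single", "st_combined", "mt")) {
    ref <- gxepred:::scheme_reference(s, yt, yo, val)
    all_ref <- unlist(lapply(ref, names))
    expect_length(intersect(all_ref, val), 0)
  }
  ## a validation id hidden in the other population triggers a hard error
  yo_bad <- c(yo, yt[2])
  expect_error(gxepred:::scheme_reference("st_combined", yt, yo_bad,
                                          names(yt)[1:4]), "leakage")
})

test_that("cross-validation grid is reproducible and shares validation sets", {
  sim <- small_gxe_sim()
  yc <- yc_pipeline(sim, "GT",
                    vc = list(pop1 = list(sigma2_a = 4, sigma2_litter = 1,
                                          sigma2_e = 7),
                              pop2 = list(sigma2_a = 4, sigma2_litter = 1,
                                          sigma2_e = 6)))$yc
  geno <- impute_missing(merge_genotypes(sim$geno1, sim$geno2), "mean_dosage")
  res <- run_cv(geno, yc, "pop2", models = "gblup", n_reps = 2, k = 4,
                master_seed = 5)
  res2 <- run_cv(geno, yc, "pop2", models = "gblup", n_reps = 2, k = 4,
                 master_seed = 5)
  expect_equal(res$accuracy, res2$accuracy, tolerance = 1e-12)
  ## every target individual validated exactly once per replicate
  n_target <- sum(yc$pop == "pop2" & !is.na(yc$yc))
  per_rep <- aggregate(n_val ~ replicate + scheme, data = res, FUN = sum)
  expect_true(all(per_rep$n_val == n_target))
  ## fold sizes match across schemes within a replicate (same validation sets)
  wide <- reshape(res[res$model == "gblup", c("replicate", "fold", "scheme", "n_val")],
                  direction = "wide", idvar = c("replicate", "fold"),
                  timevar = "scheme")
  expect_equal(wide$n_val.st_single, wide$n_val.mt)
  expect_equal(wide$n_val.st_combined, wide$n_val.mt)
})

test_that("summaries and paired tests behave on forced inputs", {
  ## two identical schemes: p = 1, zero difference
  base <- expand.grid(replicate = 1:6, fold = 1:2)
  acc <- rnorm(nrow(base), 0.3, 0.02)
  res <- rbind(
    data.frame(base, scheme = "st_single", model = "gblup", accuracy = acc,
               unbiasedness = 1, n_val = 10, defined = TRUE),
    data.frame(base, scheme = "mt", model = "gblup", accuracy = acc,
               unbiasedness = 1, n_val = 10, defined = TRUE))
  s <- summarize_and_test(res)
  expect_equal(s$pairwise$p_value, 1)
  expect_equal(s$pairwise$delta_accuracy, 0)
  ## both schemes share the same significance letter
  expect_equal(unique(s$table$letters), "a")
  ## a constant +0.02 shift is significant with the paired test
  res$accuracy[res$scheme == "mt"] <- acc + 0.02
  s2 <- summarize_and_test(res)
  expect_lt(s2$pairwise$p_value, 0.05)
  expect_equal(s2$pairwise$delta_accuracy[1],
               ifelse(s2$pairwise$scheme_a[1] == "mt", 0.02, -0.02),
               tolerance = 1e-12)
  expect_equal(sort(unique(s2$table$letters)), c("a", "b"))
  ## mismatched replicate sets are rejected
  bad <- res[!(res$scheme == "mt" & res$replicate == 6), ]
  expect_error(summarize_and_test(bad), "mismatched replicate")
})
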