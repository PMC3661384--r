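test_that("design matrices follow the genotypic and additive codings", {
  de <- build_design(c(0, 1, 2, 1), spec = design_spec("genotypic"))
  expect_equal(unname(de$X_full[, 2]), c(0, 1, 0, 1))
  expect_equal(unname(de$X_full[, 3]), c(0, 0, 1, 0))
  expect_equal(de$df_hyp, 2L)

  de2 <- build_design(c(0, 1, 0, 1), spec = design_spec("genotypic"))
  expect_equal(ncol(de2$X_full), 2L)
  expect_equal(unname(de2$X_full[, 2]), c(0, 1, 0, 1))
  expect_equal(de2$df_hyp, 1L)

  de3 <- build_design(c(0, 1, 2), spec = design_spec("additive"))
  expect_equal(unname(de3$X_full[, 2]), c(0, 1, 2))
  expect_equal(de3$df_hyp, 1L)

  expect_error(build_design(rep(1, 5)), class = "mvgwas_degenerate")
})

test_that("SSCP matrices match the brute-force hat-matrix computation", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 12; p <- 2
    g <- sample(0:2, n, replace = TRUE)
    while (length(unique(g)) < 3) g <- sample(0:2, n, replace = TRUE)
    Z <- matrix(rnorm(n), n, 1)          # one covariate
    Y <- matrix(rnorm(n * p), n, p)
    de <- build_design(g, Z, design_spec())
    sscp <- fit_sscp(Y, de$X_full, de$X_reduced)
    E_ref <- sscp_by_hat(Y, de$X_full)
    H_ref <- sscp_by_hat(Y, de$X_reduced) - E_ref
    expect_lt(max(abs(sscp$E - E_ref)), 1e-10)
    expect_lt(max(abs(sscp$H - H_ref)), 1e-10)
    expect_equal(sscp$df_err, n - ncol(de$X_full))
    expect_equal(sscp$df_hyp, 2L)
  }

  ## Y exactly linear in X_full -> E = 0; X_full = X_reduced -> H = 0
  X <- cbind(1, c(0, 1, 2, 1, 0, 2))
  Y <- X %*% matrix(c(1, 2, 0.5, -1), 2, 2)
  s0 <- fit_sscp(Y, X, X[, 1, drop = FALSE])
  expect_lt(max(abs(s0$E)), 1e-20)
  Yr <- Y + rnorm(length(Y))
  s1 <- fit_sscp(Yr, X, X)
  expect_lt(max(abs(s1$H)), 1e-10)
})

test_that("Pillai trace handles the scalar, zero and boundary cases", {
  expect_equal(pillai_trace(list(H = matrix(0, 2, 2), E = diag(2),
                                 df_hyp = 2, p = 2)), 0)
  expect_equal(pillai_trace(list(H = matrix(3), E = matrix(1),
                                 df_hyp = 2, p = 1)), 0.75)
  expect_equal(pillai_trace(list(H = diag(2), E = matrix(0, 2, 2),
                                 df_hyp = 2, p = 2)), 2)
  expect_error(pillai_trace(list(H = matrix(0, 2, 2), E = matrix(0, 2, 2),
                                 df_hyp = 2, p = 2)), "positive definite")
})

test_that("Pillai statistic and F match stats::manova on random data", {
  set.seed(22)
  for (rep in 1:4) {
    n <- 40; p <- 3
    g <- sample(0:2, n, replace = TRUE, prob = c(.25, .5, .25))
    while (length(unique(g)) < 3) g <- sample(0:2, n, replace = TRUE)
    Z <- cbind(rnorm(n), rnorm(n))
    Y <- matrix(rnorm(n * p), n, p) + 0.3 * g
    st <- mvgwas:::pillai_test_stat(Y, g, Z)
    sm <- summary(stats::manova(Y ~ Z + factor(g)), test = "Pillai")$stats
    expect_equal(st[["statistic"]], sm["factor(g)", "Pillai"], tolerance = 1e-10)
    expect_equal(st[["F"]], sm["factor(g)", "approx F"], tolerance = 1e-10)
    expect_equal(st[["p"]], sm["factor(g)", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("with one response the Pillai pipeline equals the ANCOVA F test", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 30
    g <- sample(0:2, n, replace = TRUE)
    while (length(unique(g)) < 3) g <- sample(0:2, n, replace = TRUE)
    Z <- cbind(z1 = rnorm(n), z2 = runif(n))
    y <- 0.5 * Z[, 1] + 0.2 * g + rnorm(n)
    st <- mvgwas:::pillai_test_stat(matrix(y), g, Z)
    a <- anova(lm(y ~ Z + factor(g)))
    expect_equal(st[["F"]], a["factor(g)", "F value"], tolerance = 1e-10)
    expect_equal(st[["p"]], a["factor(g)", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(st[["df1"]], 2)
    expect_equal(st[["df2"]], a["Residuals", "Df"])
  }
})

test_that("the F approximation handles V = 0 and boundary V", {
  fa <- pillai_f_approx(0, p = 3, df_hyp = 2, df_err = 30)
  expect_equal(fa$F, 0)
  expect_equal(fa$p_value, 1)
  fb <- pillai_f_approx(2, p = 3, df_hyp = 2, df_err = 30)
  expect_equal(fb$note, "boundary_statistic")
  expect_gt(fb$p_value, 0)
  expect_error(pillai_f_approx(0.5, p = 6, df_hyp = 2, df_err = 4), "df_err")
})

test_that("the test is invariant to response location and positive scale", {
  cfg <- small_config(effect_size = 0.5, n = 80)
  s <- sim_parts(cfg, seed = 24)
  st0 <- mvgwas:::pillai_test_stat(s$Y, s$g)
  Y2 <- s$Y * 3.7
  Y2[, 2] <- Y2[, 2] + 11
  st1 <- mvgwas:::pillai_test_stat(Y2, s$g)
  expect_equal(st0[["statistic"]], st1[["statistic"]], tolerance = 1e-12)
  expect_equal(st0[["p"]], st1[["p"]], tolerance = 1e-12)
})

test_that("test_snp skips degenerate SNPs and respects per-SNP missingness", {
  cfg <- small_config(effect_size = 0, n = 40)
  ds <- fixture_dataset(cfg, seed = 25, m = 4, missing_rate = 0.1)
  ## make SNP 2 monomorphic
  ds$genotype$counts[, 2] <- 0
  r2 <- test_snp(ds, 2)
  expect_equal(r2$note, "monomorphic")
  expect_true(is.na(r2$p_value))
  r3 <- test_snp(ds, 3)
  expect_equal(r3$n_used, sum(!is.na(ds$genotype$counts[, 3])))
  expect_true(r3$statistic >= 0 && r3$statistic <= min(6, r3$df1))
})

test_that("a strong simulated signal is detected at genome-wide strength", {
  cfg <- small_config(effect_size = 1, n = 500)
  s <- sim_parts(cfg, seed = 26)
  st <- mvgwas:::pillai_test_stat(s$Y, s$g)
  expect_lt(st[["p"]], 1e-6)
})

test_that("run_gwas streams the per-SNP test in .bim order", {
  cfg <- small_config(effect_size = 0.5, n = 50)
  ds <- fixture_dataset(cfg, seed = 27, m = 6, missing_rate = 0.05)
  res <- run_gwas(ds)
  expect_equal(nrow(res), 6L)
  expect_equal(res$snp, ds$genotype$snps$snp_id)
  for (j in c(1L, 4L, 6L)) {
    rj <- as.data.frame(res[j, ]); rownames(rj) <- NULL
    expect_identical(rj, test_snp(ds, j))
  }
  ## Pillai trace bounded by s = min(p, df_hyp) on every output
  ok <- !is.na(res$statistic)
  expect_true(all(res$statistic[ok] >= 0 & res$statistic[ok] <= 2 + 1e-12))
})

test_that("permutation and asymptotic p-values agree on a null dataset", {
  cfg <- small_config(effect_size = 0, n = 500)
  s <- sim_parts(cfg, seed = 28)
  st <- mvgwas:::pillai_test_stat(s$Y, s$g)
  set.seed(29)
  perm_F <- replicate(2000, {
    mvgwas:::pillai_test_stat(s$Y, sample(s$g))[["F"]]
  })
  p_perm <- (1 + sum(perm_F >= st[["F"]])) / 2001
  expect_lt(abs(p_perm - st[["p"]]), 0.02)
})

test_that("a 1000-SNP null fixture rejects at the nominal rate", {
  cfg <- small_config(effect_size = 0, n = 150)
  ds <- fixture_dataset(cfg, seed = 30, m = 1000)
  res <- run_gwas(ds)
  expect_equal(nrow(res), 1000L)
  frac <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / 1000))
})
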