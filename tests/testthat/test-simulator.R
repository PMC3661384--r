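test_that("genotypes follow Hardy-Weinberg proportions and are reproducible", {
  g <- sample_genotypes(10000, maf = 0.5, seed = 51)
  cnt <- tabulate(g + 1L, 3L)
  for (k in 1:3) {
    p <- c(0.25, 0.5, 0.25)[k]
    expect_lt(abs(cnt[k] - 10000 * p), 4 * sqrt(10000 * p * (1 - p)))
  }
  expect_identical(sample_genotypes(100, 0.3, seed = 52),
                   sample_genotypes(100, 0.3, seed = 52))
  g0 <- sample_genotypes(2000, maf = 1e-9, seed = 53)
  expect_true(all(g0 == 0))
  expect_error(sample_genotypes(10, 0.7), "maf")
  expect_error(sample_genotypes(10, 0), "maf")
})

test_that("effect sizes interpolate the genotype mean differences linearly", {
  mp <- mean_profiles(1:2, mu0 = c(0, 0), mu1 = c(2, 4), mu2 = c(3, 1))
  e0 <- effect_means(mp, 0)
  expect_equal(e0$mu1, e0$mu0)
  expect_equal(e0$mu2, e0$mu0)
  e1 <- effect_means(mp, 1)
  expect_equal(e1$mu1, c(2, 4))
  e5 <- effect_means(mp, 0.5)
  expect_equal(e5$mu1, c(1, 2))
  ## separation is exactly ES * the full separation
  for (es in c(0.2, 0.7)) {
    ee <- effect_means(mp, es)
    expect_equal(sqrt(sum((ee$mu2 - ee$mu0)^2)),
                 es * sqrt(sum((mp$mu2 - mp$mu0)^2)))
  }
})

test_that("covariance constructors produce the stated positive-definite matrices", {
  S <- build_covariance(covariance_spec("autoregressive", rho = 0.5), 3)
  expect_equal(S, rbind(c(1, .5, .25), c(.5, 1, .5), c(.25, .5, 1)))
  S2 <- build_covariance(covariance_spec("compound_symmetric", rho = 0.75), 6)
  expect_true(all(S2[upper.tri(S2)] == 0.75))
  expect_equal(diag(S2), rep(1, 6))
  expect_equal(build_covariance(covariance_spec("independent", sds = 2), 4),
               diag(4, 4))
  expect_error(build_covariance(covariance_spec("compound_symmetric", rho = -0.5), 6),
               "rho")
  ## minimum eigenvalue stays positive across the valid rho ranges
  for (rho in c(-0.15, 0.25, 0.5, 0.75, 0.95)) {
    for (fam in c("compound_symmetric", "autoregressive")) {
      if (fam == "compound_symmetric" && rho <= -1 / 5) next
      S <- build_covariance(covariance_spec(fam, rho = rho,
                                            sds = c(1, 2, 1, 3, 1, 2)), 6)
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("simulated datasets are deterministic and match their error family", {
  cfg <- small_config(effect_size = 0.4, n = 50)
  s1 <- simulate_dr(cfg, seed = 54)
  s2 <- simulate_dr(cfg, seed = 54)
  expect_identical(s1$Y, s2$Y)
  expect_identical(s1$genotype_counts, s2$genotype_counts)

  ## centered gamma: mean 0, variance shape * scale^2 = 0.125
  cfgg <- small_config(effect_size = 0, n = 20000,
                       errors = error_family("gamma_centered"))
  sg <- simulate_dr(cfgg, seed = 55)
  err <- sg$Y - rep(cfgg$means$mu0, each = nrow(sg$Y))
  ndraw <- length(err)
  expect_lt(abs(mean(err)), 4 * sqrt(0.125 / ndraw))
  sd_var <- 0.125 * sqrt((3.75 - 1) / ndraw)  # gamma excess kurtosis 6/8
  expect_lt(abs(var(as.vector(err)) - 0.125), 4 * sd_var)

  ## laplace: variance 2 b^2 and excess kurtosis about 3
  cfgl <- small_config(effect_size = 0, n = 20000,
                       errors = error_family("laplace", laplace_scale = 0.1))
  sl <- simulate_dr(cfgl, seed = 56)
  e <- as.vector(sl$Y - rep(cfgl$means$mu0, each = nrow(sl$Y)))
  expect_equal(var(e), 2 * 0.1^2, tolerance = 0.05)
  exk <- mean(e^4) / var(e)^2 - 3
  expect_gt(exk, 2.5); expect_lt(exk, 3.5)
})

test_that("replicates share their individual's genotype and mean", {
  sig <- synthetic_signal(1)
  cfg <- simulation_config(sig$means, sig$covariance, effect_size = 1,
                           n = 30, replicates = 3)
  s <- simulate_dr(cfg, seed = 57)
  expect_equal(nrow(s$Y), 90)
  expect_equal(s$individual, rep(1:30, each = 3))
})

test_that("the synthetic signal has the advertised shape", {
  s0 <- synthetic_signal(0)
  expect_equal(s0$means$mu0, s0$means$mu1)
  expect_equal(s0$means$mu0, s0$means$mu2)
  s1 <- synthetic_signal(1)
  for (mu in list(s1$means$mu0, s1$means$mu1, s1$means$mu2))
    expect_true(all(diff(mu) < 0))       # monotone decreasing viability
  sep1 <- sqrt(sum((s1$means$mu1 - s1$means$mu0)^2))
  sep2 <- sqrt(sum((s1$means$mu2 - s1$means$mu0)^2))
  expect_gt(sep2, sep1)                   # separation grows with allele count
  s2 <- synthetic_signal(2)
  expect_gt(sqrt(sum((s2$means$mu2 - s2$means$mu0)^2)), sep2)
  S <- build_covariance(s1$covariance, 6)
  R <- cov2cor(S)
  off <- R[upper.tri(R)]
  expect_true(all(off > 0.35 & off < 0.95)) # strong, distance-decaying
  expect_gt(min(eigen(S, only.values = TRUE)$values), 0)
})

test_that("hill populations shift only the designated parameter", {
  ## noiseless, zero-spread population: curves identical within genotype
  hp <- hill_population(n = 30, maf = 0.5,
                        param_sd = c(min = 0, max = 0, log_ic50 = 0, slope = 0),
                        shift_param = "log_ic50", shift = 0.3,
                        laplace_scale = 0, seed = 58)
  for (gg in unique(hp$genotype_counts)) {
    rows <- hp$Y[hp$genotype_counts == gg, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
  ## group mean curves are horizontal displacements: fitted IC50 moves,
  ## Min/Max stay
  fits <- lapply(sort(unique(hp$genotype_counts)), function(gg)
    fit_hill(hp$doses, colMeans(hp$Y[hp$genotype_counts == gg, , drop = FALSE])))
  lic <- sapply(fits, function(f) log10(f$ic50))
  expect_equal(diff(lic), rep(0.3, length(lic) - 1), tolerance = 1e-4)
  expect_lt(diff(range(sapply(fits, `[[`, "min_asymptote"))), 1e-4)
  expect_lt(diff(range(sapply(fits, `[[`, "max_asymptote"))), 1e-4)
})

test_that("summary-driven mean profiles vary only their named summary", {
  m0 <- summary_driven_means("IC50", shift = 0)
  expect_equal(m0$mu0, m0$mu1)
  expect_equal(m0$mu0, m0$mu2)

  mi <- summary_driven_means("IC50")
  fits <- lapply(list(mi$mu0, mi$mu1, mi$mu2), function(mu) fit_hill(mi$doses, mu))
  lic <- sapply(fits, function(f) log10(f$ic50))
  expect_equal(diff(lic), rep(0.01, 2), tolerance = 1e-3)
  expect_lt(diff(range(sapply(fits, `[[`, "min_asymptote"))), 1e-3)
  expect_lt(diff(range(sapply(fits, `[[`, "max_asymptote"))), 1e-3)

  ma <- summary_driven_means("AUC")
  a <- sapply(list(ma$mu0, ma$mu1, ma$mu2), function(mu) auc_empirical(ma$doses, mu))
  span <- max(ma$doses) - min(ma$doses)
  expect_equal(diff(a), rep(-0.02 * span, 2), tolerance = 1e-10)

  ms <- summary_driven_means("Slope")
  fs <- lapply(list(ms$mu0, ms$mu1, ms$mu2), function(mu) fit_hill(ms$doses, mu))
  expect_equal(sapply(fs, `[[`, "slope"), c(2.5, 2.62, 2.74), tolerance = 1e-3)
})
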