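## shared builders for the test suite

## a small correlated 6-dose generating model
small_config <- function(effect_size = 0, n = 60, maf = 0.5, strength = 1,
                         errors = error_family("gaussian")) {
  sig <- synthetic_signal(strength)
  simulation_config(sig$means, sig$covariance, errors,
                    effect_size = effect_size, n = n, maf = maf)
}

## simulate one dataset and return its parts
sim_parts <- function(config, seed) {
  s <- simulate_dr(config, seed = seed)
  list(Y = s$Y, g = s$genotype_counts, doses = s$doses)
}

## brute-force residual SSCP through explicit hat matrices
sscp_by_hat <- function(Y, X) {
  P <- X %*% solve(crossprod(X)) %*% t(X)
  R <- (diag(nrow(Y)) - P) %*% Y
  crossprod(R)
}

## build an aligned dataset from an in-memory fixture
fixture_dataset <- function(config, seed, m = 5, missing_rate = 0,
                            covariates = FALSE, doses = NULL) {
  prefix <- tempfile("fx")
  fx <- write_fixture(config, seed = seed, prefix = prefix, m = m,
                      missing_rate = missing_rate, covariates = covariates)
  geno <- read_plink(prefix)
  pheno <- read_phenotype_table(fx$pheno, doses = doses)
  covar <- if (covariates) read_covariate_table(fx$covar) else NULL
  suppressMessages(align_data(geno, pheno, covar))
}
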