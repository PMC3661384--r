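# Dose-response simulation: genotype sampling under HWE, genotype-specific
# mean profiles with a scalar effect size, structured covariances, gaussian /
# centered-gamma / Laplace error families, and the study generators (the
# 6-dose correlated signal emulator, hill-parameter populations, and 12-dose
# summary-driven alternatives).

#' Genotype-specific mean profiles
#'
#' @param doses vector of d concentrations (ascending).
#' @param mu0,mu1,mu2 mean response vectors (length d) for 0, 1 and 2 minor
#'   alleles.
#' @return object of class `mean_profiles`.
#' @export
mean_profiles <- function(doses, mu0, mu1, mu2) {
  stopifnot(length(mu0) == length(doses), length(mu1) == length(doses),
            length(mu2) == length(doses))
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be strictly increasing")
  structure(list(doses = doses, mu0 = mu0, mu1 = mu1, mu2 = mu2),
            class = "mean_profiles")
}

#' Scale genotype mean differences by an effect size
#'
#' The genotype effects are the differences from the reference profile,
#' beta_m = mu_m - mu_0; an effect size ES in [0, 1] interpolates between the
#' null (ES = 0, all genotypes share mu_0) and the full observed differences
#' (ES = 1).
#'
#' @param means a [mean_profiles()] object.
#' @param effect_size scalar >= 0.
#' @return `mean_profiles` with `mu_i = mu_0 + ES * (mu_i - mu_0)`.
#' @export
effect_means <- function(means, effect_size) {
  stopifnot(inherits(means, "mean_profiles"), effect_size >= 0)
  mean_profiles(means$doses, means$mu0,
                means$mu0 + effect_size * (means$mu1 - means$mu0),
                means$mu0 + effect_size * (means$mu2 - means$mu0))
}

#' Specify a residual covariance structure
#'
#' @param family `"independent"`, `"compound_symmetric"`, `"autoregressive"`
#'   or `"empirical"` (an explicit matrix).
#' @param rho correlation parameter: constant pairwise correlation for
#'   compound symmetry (valid above -1/(d-1)), lag-decay base for the
#'   autoregressive family (`cor(i, j) = rho^|i-j|`, |rho| < 1).
#' @param sds per-dose standard deviations (recycled to length d).
#' @param matrix explicit d x d covariance, `family = "empirical"` only.
#' @return object of class `covariance_spec`.
#' @export
covariance_spec <- function(family = c("independent", "compound_symmetric",
                                       "autoregressive", "empirical"),
                            rho = 0, sds = 1, matrix = NULL) {
  family <- match.arg(family)
  if (family == "empirical" && is.null(matrix))
    stop("family = 'empirical' needs an explicit matrix")
  structure(list(family = family, rho = rho, sds = sds, matrix = matrix),
            class = "covariance_spec")
}

#' Build the residual covariance matrix
#'
#' @param spec a [covariance_spec()].
#' @param d number of responses.
#' @return d x d positive-definite covariance matrix.
#' @export
build_covariance <- function(spec, d) {
  stopifnot(inherits(spec, "covariance_spec"))
  if (spec$family == "empirical") {
    S <- spec$matrix
    if (!all(dim(S) == d)) stop("empirical matrix is not d x d")
  } else {
    R <- switch(spec$family,
      independent = diag(d),
      compound_symmetric = {
        if (spec$rho <= -1 / (d - 1) || spec$rho >= 1)
          stop(sprintf("compound-symmetric rho must be in (-1/(d-1), 1) = (%.4f, 1)",
                       -1 / (d - 1)))
        M <- matrix(spec$rho, d, d); diag(M) <- 1; M
      },
      autoregressive = {
        if (abs(spec$rho) >= 1) stop("autoregressive rho must be in (-1, 1)")
        spec$rho^abs(outer(seq_len(d), seq_len(d), "-"))
      })
    sds <- rep_len(spec$sds, d)
    S <- R * (sds %o% sds)
  }
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance is not positive definite; eigenvalues: ",
         paste(signif(ev, 4), collapse = ", "))
  S
}

#' Specify the error family
#'
#' @param kind `"gaussian"` (multivariate normal with the full covariance),
#'   `"gamma_centered"` (components i.i.d. `Gamma(shape, scale) - shape*scale`,
#'   independent across doses) or `"laplace"` (components i.i.d.
#'   `Laplace(0, scale)`).
#' @param gamma_shape,gamma_scale gamma parameters (defaults 8 and 0.125, so
#'   the component variance is `8 * 0.125^2 = 0.125`).
#' @param laplace_scale Laplace scale b (variance `2 b^2`).
#' @return object of class `error_family`.
#' @export
error_family <- function(kind = c("gaussian", "gamma_centered", "laplace"),
                         gamma_shape = 8, gamma_scale = 0.125,
                         laplace_scale = NULL) {
  structure(list(kind = match.arg(kind), gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale, laplace_scale = laplace_scale),
            class = "error_family")
}

rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Full recipe for one simulated dose-response dataset
#'
#' @param means a [mean_profiles()] object.
#' @param covariance a [covariance_spec()] (used by the gaussian family).
#' @param errors an [error_family()].
#' @param effect_size ES in `[0, 1]` scaling the genotype differences.
#' @param n number of individuals.
#' @param maf minor allele frequency in (0, 0.5].
#' @param replicates technical replicates per individual (Eq.-style index k).
#' @param seed optional integer; when set, [simulate_dr()] is deterministic.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(means, covariance = covariance_spec("independent"),
                              errors = error_family("gaussian"),
                              effect_size = 0, n = 500L, maf = 0.5,
                              replicates = 1L, seed = NULL) {
  stopifnot(inherits(means, "mean_profiles"), effect_size >= 0,
            n >= 2, replicates >= 1)
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  structure(list(means = means, covariance = covariance, errors = errors,
                 effect_size = effect_size, n = as.integer(n), maf = maf,
                 replicates = as.integer(replicates), seed = seed,
                 rng = "Mersenne-Twister"),
            class = "sim_config")
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' P(0, 1, 2 minor alleles) = ((1-q)^2, 2q(1-q), q^2) with q = `maf`.
#'
#' @param n number of individuals.
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional integer seed.
#' @return integer vector of minor-allele counts.
#' @export
sample_genotypes <- function(n, maf, seed = NULL) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  sample(0:2, n, replace = TRUE,
         prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
}

#' Simulate one dose-response dataset
#'
#' Per individual j with genotype i, draws `replicates` response vectors
#' `Y = mu_i(ES) + e` where `mu_i(ES)` comes from [effect_means()] and the
#' error is multivariate normal with the configured covariance, i.i.d.
#' centered gamma, or i.i.d. Laplace, per the error family.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return list with `genotype_counts` (length n), `Y` ((n * replicates) x d),
#'   `individual` (row-to-individual index), `doses`, and `config`.
#' @export
simulate_dr <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  d <- length(config$means$doses)
  g <- sample_genotypes(config$n, config$maf)
  mu <- effect_means(config$means, config$effect_size)
  M <- rbind(mu$mu0, mu$mu1, mu$mu2)
  idx <- rep(seq_len(config$n), each = config$replicates)
  N <- length(idx)
  err <- switch(config$errors$kind,
    gaussian = {
      R <- chol(build_covariance(config$covariance, d))
      matrix(stats::rnorm(N * d), N, d) %*% R
    },
    gamma_centered = {
      sh <- config$errors$gamma_shape; sc <- config$errors$gamma_scale
      matrix(stats::rgamma(N * d, shape = sh, scale = sc) - sh * sc, N, d)
    },
    laplace = {
      b <- config$errors$laplace_scale
      if (is.null(b)) stop("laplace_scale is not set")
      matrix(rlaplace(N * d, b), N, d)
    })
  Y <- M[g[idx] + 1L, , drop = FALSE] + err
  dimnames(Y) <- NULL
  list(genotype_counts = g, Y = Y, individual = idx,
       doses = config$means$doses, config = config)
}

#' Correlated 6-dose signal emulator
#'
#' A synthetic stand-in for a strong real pharmacogenomic signal: three
#' monotone-decreasing sigmoid viability curves over six 2-fold-diluted
#' concentrations whose separation grows with minor-allele count and with
#' `strength`.  The per-allele difference combines a small log-IC50 shift
#' with a vertical bump concentrated at intermediate doses, because observed
#' genotype differences concentrate where the curve is steep and are not
#' summarizable by a single curve parameter.  The covariance has per-dose
#' standard deviations largest mid-curve (0.08-0.18) and strong positive
#' correlations (about 0.4-0.9) decaying with dose distance.
#'
#' @param strength effect scale; 0 gives identical curves.
#' @return list with `means` (a [mean_profiles()]) and `covariance`
#'   (an empirical [covariance_spec()]).
#' @export
synthetic_signal <- function(strength = 1) {
  stopifnot(strength >= 0)
  doses <- c(0.5, 1, 2, 4, 8, 16)
  bump <- c(0.005, 0.02, 0.045, 0.035, 0.015, 0.005)
  curve_g <- function(g)
    hill_response(doses, min = 0.08, max = 1,
                  ic50 = 10^(log10(2) + 0.04 * strength * g), slope = 1.6) +
      bump * strength * g
  mu0 <- curve_g(0)
  v <- mu0
  sds <- 0.08 + 0.4 * v * (1 - v)
  lag <- abs(outer(1:6, 1:6, "-"))
  R <- 0.35 + 0.65 * 0.8^lag
  diag(R) <- 1
  list(means = mean_profiles(doses, mu0, curve_g(1), curve_g(2)),
       covariance = covariance_spec("empirical", matrix = R * (sds %o% sds)))
}

#' Simulate dose-response curves from genotype-dependent hill parameters
#'
#' Per individual, hill parameters (Min, Max, log10 IC50, Slope) are drawn
#' from normal distributions whose mean for one designated parameter shifts
#' with minor-allele count; the curve is evaluated on the dose grid and
#' i.i.d. Laplace errors are added.  This reproduces the curve-population
#' style of generator with heavy-tailed errors.
#'
#' @param n individuals; `maf` minor allele frequency.
#' @param doses dose grid (default a 12-point 2-fold dilution series).
#' @param base named vector of population means
#'   `c(min, max, log_ic50, slope)`.
#' @param param_sd named vector of population sds for the same parameters.
#' @param shift_param which parameter mean shifts with genotype:
#'   `"min"`, `"max"`, `"log_ic50"` or `"slope"`.
#' @param shift per-allele shift of that parameter's mean.
#' @param laplace_scale Laplace error scale (default 0.05/sqrt(2), matching a
#'   gaussian sd of 0.05).
#' @param maf minor allele frequency.
#' @param seed optional integer seed.
#' @return as [simulate_dr()]: list with `genotype_counts`, `Y`, `doses`,
#'   plus `params`, the n x 4 matrix of drawn hill parameters.
#' @export
hill_population <- function(n = 500L, maf = 0.5, doses = 2^(0:11),
                            base = c(min = 0.1, max = 1,
                                     log_ic50 = mean(range(log10(doses))),
                                     slope = 2.5),
                            param_sd = c(min = 0.01, max = 0.02,
                                         log_ic50 = 0.15, slope = 0.25),
                            shift_param = c("log_ic50", "min", "max", "slope"),
                            shift = 0.15, laplace_scale = 0.05 / sqrt(2),
                            seed = NULL) {
  shift_param <- match.arg(shift_param)
  req <- c("min", "max", "log_ic50", "slope")
  if (!all(req %in% names(base)) || !all(req %in% names(param_sd)))
    stop("base and param_sd must name min, max, log_ic50 and slope")
  if (any(param_sd < 0) || laplace_scale < 0) stop("negative scale parameter")
  if (!is.null(seed)) set.seed(seed)
  g <- sample_genotypes(n, maf)
  P <- sapply(req, function(p) stats::rnorm(n, base[[p]], param_sd[[p]]))
  P[, shift_param] <- P[, shift_param] + shift * g
  ld <- log10(doses)
  F <- 1 / (1 + 10^(P[, "slope"] * outer(rep(1, n), ld) -
                      P[, "slope"] * P[, "log_ic50"]))
  Y <- P[, "min"] + (P[, "max"] - P[, "min"]) * F +
    matrix(rlaplace(n * length(ld), laplace_scale), n)
  list(genotype_counts = g, Y = Y, individual = seq_len(n), doses = doses,
       params = P)
}

#' Mean profiles whose genotype differences follow one univariate summary
#'
#' Builds genotype mean curves from a base four-parameter logistic over a
#' 2-fold dilution series of `d` doses (equal spacing on the log scale) such
#' that only the named summary differs between genotypes: a uniform vertical
#' offset for `"AUC"`, or a per-allele shift of the corresponding hill
#' parameter for `"Min"`, `"IC50"` (on log10 scale) and `"Slope"`.
#'
#' Default shifts are calibrated so that, with the companion residual model
#' (autoregressive rho = 0.25, sd 0.05), association power at n = 500 sits in
#' the informative mid-range rather than at 0 or 1.
#'
#' @param summary one of `"AUC"`, `"Min"`, `"IC50"`, `"Slope"`.
#' @param d number of doses (default 12).
#' @param shift per-allele shift; `NULL` uses the summary-specific default
#'   (AUC -0.02 response units, Min 0.025, IC50 0.01 log10 units,
#'   Slope 0.12).
#' @return a [mean_profiles()]; attributes `base` (the base 4PL parameters)
#'   and `summary`.
#' @export
summary_driven_means <- function(summary = c("AUC", "Min", "IC50", "Slope"),
                                 d = 12L, shift = NULL) {
  summary <- match.arg(summary)
  doses <- 2^(seq_len(d) - 1L)
  base <- list(min = 0.1, max = 1, log_ic50 = mean(range(log10(doses))),
               slope = 2.5)
  if (is.null(shift))
    shift <- switch(summary, AUC = -0.02, Min = 0.025, IC50 = 0.01, Slope = 0.12)
  curve_g <- function(g) {
    p <- base
    switch(summary,
      AUC = hill_response(doses, p$min, p$max, 10^p$log_ic50, p$slope) + shift * g,
      Min = hill_response(doses, p$min + shift * g, p$max, 10^p$log_ic50, p$slope),
      IC50 = hill_response(doses, p$min, p$max, 10^(p$log_ic50 + shift * g), p$slope),
      Slope = hill_response(doses, p$min, p$max, 10^p$log_ic50, p$slope + shift * g))
  }
  out <- mean_profiles(doses, curve_g(0), curve_g(1), curve_g(2))
  attr(out, "base") <- base
  attr(out, "summary") <- summary
  out
}

#' Write an on-disk synthetic fixture
#'
#' Generates `m` SNPs (the first follows the configured MAF and carries the
#' phenotype association; the rest are independent null SNPs with MAFs drawn
#' uniformly on [0.05, 0.5]) plus an Eq.-style phenotype table from the
#' configured generating model, and writes a PLINK trio, a phenotype table
#' and (optionally) a covariate table.  Deterministic given `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param prefix output path prefix.
#' @param m number of SNPs.
#' @param missing_rate fraction of genotype calls set missing at random.
#' @param covariates write a small covariate table (one numeric growth-rate
#'   column and one nominal batch column) that does not enter the phenotype
#'   model.
#' @return invisible list with the simulated truth: `counts` (minor-allele
#'   count matrix actually written), `phenotype` (the n x d matrix), `g`
#'   (causal genotype), and the file paths.
#' @export
write_fixture <- function(config, seed, prefix, m = 10L, missing_rate = 0,
                          covariates = FALSE) {
  stopifnot(inherits(config, "sim_config"), m >= 1)
  set.seed(seed)
  sim <- simulate_dr(config, seed = seed + 1L)
  n <- config$n
  counts <- matrix(NA_real_, n, m)
  counts[, 1L] <- sim$genotype_counts
  if (m > 1L) {
    mafs <- stats::runif(m - 1L, 0.05, 0.5)
    for (j in seq_len(m - 1L))
      counts[, j + 1L] <- sample_genotypes(n, mafs[j])
  }
  if (missing_rate > 0) {
    drop <- which(stats::runif(n * m) < missing_rate)
    counts[drop] <- NA
  }
  ## orient every column to its observed minor allele (sampling can push the
  ## realized frequency of a maf = 0.5 SNP above 0.5), so that the written
  ## allele1 is always the allele read_plink will report as minor
  flip <- colMeans(counts, na.rm = TRUE) / 2 > 0.5
  flip[is.na(flip)] <- FALSE
  counts[, flip] <- 2 - counts[, flip, drop = FALSE]
  samples <- data.frame(fid = paste0("F", seq_len(n)),
                        iid = paste0("I", seq_len(n)),
                        stringsAsFactors = FALSE)
  snps <- data.frame(chromosome = "1", snp_id = paste0("snp", seq_len(m)),
                     genetic_distance = 0, position = seq_len(m) * 1000L,
                     allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  ## written counts count allele1 ("A"), i.e. A is the counted allele
  write_plink(counts, samples, snps, prefix)
  Yround <- sim$Y[match(seq_len(n), sim$individual), , drop = FALSE]
  ph <- data.frame(FID = samples$fid, IID = samples$iid,
                   round(Yround, 6))
  names(ph)[-(1:2)] <- paste0("v", seq_len(ncol(Yround)))
  ph_path <- paste0(prefix, ".pheno.txt")
  utils::write.table(ph, ph_path, quote = FALSE, sep = "\t", row.names = FALSE)
  cov_path <- NULL
  if (covariates) {
    cov_path <- paste0(prefix, ".covar.txt")
    cv <- data.frame(FID = samples$fid, IID = samples$iid,
                     growth = round(stats::rnorm(n), 4),
                     batch = sample(c("b1", "b2", "b3"), n, replace = TRUE))
    utils::write.table(cv, cov_path, quote = FALSE, sep = "\t", row.names = FALSE)
  }
  g_true <- if (flip[1L]) 2 - sim$genotype_counts else sim$genotype_counts
  invisible(list(counts = counts, phenotype = Yround, g = g_true,
                 bed = paste0(prefix, ".bed"), pheno = ph_path,
                 covar = cov_path))
}
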