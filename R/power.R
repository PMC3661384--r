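# Method-comparison machinery: per-dataset statistics for all five methods,
# resampling (empirical) p-values against a simulated null, power tables,
# type-I error, Friedman cross-method comparison and QQ diagnostics.

MVGWAS_METHODS <- c("MANOVA", "IC50", "Slope", "AUC_Emp", "ANOVA_pooled")

## univariate genotypic-model F test of y on genotype (plus covariates);
## returns c(F, df1, df2, p)
genotype_anova_stat <- function(y, g, covariates = NULL) {
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  X <- if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE]
  if (length(unique(g)) < 2L)
    return(c(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_))
  de <- build_design(g, X, design_spec("genotypic"))
  qf <- qr(de$X_full); q0 <- qr(de$X_reduced)
  rss1 <- sum(qr.resid(qf, y)^2)
  rss0 <- sum(qr.resid(q0, y)^2)
  df1 <- qf$rank - q0$rank
  df2 <- length(y) - qf$rank
  if (rss0 <= .Machine$double.eps * sum(y^2))  # constant response given X
    return(c(F = 0, df1 = df1, df2 = df2, p = 1))
  Fst <- ((rss0 - rss1) / df1) / (rss1 / df2)
  c(F = Fst, df1 = df1, df2 = df2,
    p = stats::pf(Fst, df1, df2, lower.tail = FALSE))
}

#' Per-curve summary values for one phenotype matrix
#'
#' @param doses dose grid.
#' @param Y n x d response matrix.
#' @param method `"IC50"` (log10 IC50 of the per-curve hill fit), `"Slope"`
#'   (hill slope) or `"AUC_Emp"` (trapezoid AUC).
#' @param hill_fits optional precomputed [fit_hill_curves()] result (shared
#'   between the IC50 and Slope methods).
#' @return list with `values` (length n, NA where the fit failed), `failed`
#'   (indices of failed curves) and `method`.
#' @export
summarize_curves <- function(doses, Y, method = c("IC50", "Slope", "AUC_Emp"),
                             hill_fits = NULL) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (method == "AUC_Emp") {
    vals <- auc_empirical(doses, Y)
    return(list(values = vals, failed = integer(0), method = method))
  }
  hf <- if (is.null(hill_fits)) fit_hill_curves(doses, Y) else hill_fits
  vals <- if (method == "IC50") hf$log_ic50 else hf$slope
  vals[!hf$converged] <- NA_real_
  list(values = vals, failed = which(!hf$converged), method = method)
}

#' Association test on a per-curve summary
#'
#' Genotypic-model F test of the summary values on genotype, adjusted for
#' covariates; failed curves are excluded (complete case).  Identical to the
#' p = 1 MANOVA on the summary.
#'
#' @param summary a [summarize_curves()] result.
#' @param genotype_counts vector in {0, 1, 2}.
#' @param covariates optional numeric covariate matrix.
#' @return list with `statistic` (F), `df1`, `df2`, `p_value`, `n_used`,
#'   `note`.
#' @export
anova_summary_test <- function(summary, genotype_counts, covariates = NULL) {
  st <- genotype_anova_stat(summary$values, genotype_counts, covariates)
  n_used <- sum(is.finite(summary$values))
  note <- if (is.na(st[["F"]])) "degenerate" else ""
  list(statistic = st[["F"]], df1 = st[["df1"]], df2 = st[["df2"]],
       p_value = st[["p"]], n_used = n_used, note = note)
}

#' Pooled-observation ANOVA (deliberately ignoring within-curve correlation)
#'
#' Stacks all n x d observations as a univariate response with dose as a
#' nominal factor and tests the genotype factor.  When responses are
#' correlated within individual, this test's asymptotic p-values are
#' miscalibrated -- that is the point of carrying it in the comparison -- so
#' they should only be used through resampling.
#'
#' @param doses dose grid.
#' @param Y n x d response matrix.
#' @param genotype_counts vector in {0, 1, 2}.
#' @param covariates optional n x q covariate matrix (repeated across doses).
#' @return as [anova_summary_test()].
#' @export
anova_pooled_test <- function(doses, Y, genotype_counts, covariates = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); d <- ncol(Y)
  y <- as.vector(Y)
  g <- rep(genotype_counts, d)
  X <- NULL
  if (d > 1L) {
    dose_f <- gl(d, n)
    X <- stats::model.matrix(~dose_f)[, -1L, drop = FALSE]
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates[rep(seq_len(n), d), , drop = FALSE])
  }
  st <- genotype_anova_stat(y, g, X)
  note <- if (is.na(st[["F"]])) "degenerate" else ""
  list(statistic = st[["F"]], df1 = st[["df1"]], df2 = st[["df2"]],
       p_value = st[["p"]], n_used = n, note = note)
}

## Evaluate the requested methods on one simulated dataset.  Returns a named
## vector of F-scale statistics (larger = more extreme) and, as an attribute,
## the asymptotic p-values.
method_statistics <- function(doses, Y, g, methods = MVGWAS_METHODS,
                              hill_grid_obj = NULL) {
  stats_out <- p_out <- stats::setNames(rep(NA_real_, length(methods)), methods)
  hf <- NULL
  if (any(c("IC50", "Slope") %in% methods))
    hf <- fit_hill_curves(doses, Y, grid = hill_grid_obj)
  for (m in methods) {
    if (m == "MANOVA") {
      st <- pillai_test_stat(Y, g)
      stats_out[m] <- st[["F"]]; p_out[m] <- st[["p"]]
    } else if (m == "ANOVA_pooled") {
      st <- anova_pooled_test(doses, Y, g)
      stats_out[m] <- st$statistic; p_out[m] <- st$p_value
    } else {
      sm <- summarize_curves(doses, Y, if (m == "AUC_Emp") "AUC_Emp" else m,
                             hill_fits = hf)
      st <- anova_summary_test(sm, g)
      stats_out[m] <- st$statistic; p_out[m] <- st$p_value
    }
  }
  attr(stats_out, "p_asymptotic") <- p_out
  stats_out
}

config_fingerprint <- function(config) {
  cf <- config
  cf$effect_size <- NULL
  cf$seed <- NULL
  paste(deparse(cf, control = "all"), collapse = "")
}

#' Simulate a null reference distribution of method statistics
#'
#' Simulates `n_null` datasets from the configuration with the effect size
#' forced to 0 and records each method's statistic.  The null stream uses a
#' seed offset disjoint from the alternative stream.
#'
#' @param config a [simulation_config()] (any effect size; forced to 0).
#' @param methods subset of `r toString(MVGWAS_METHODS)`.
#' @param n_null number of null datasets (>= 1000 for stable tail estimates).
#' @param seed integer seed.
#' @return object of class `null_reference`: list of per-method statistic
#'   vectors plus the generating fingerprint.
#' @export
null_reference <- function(config, methods = MVGWAS_METHODS, n_null = 10000L,
                           seed = 1L) {
  config$effect_size <- 0
  doses <- config$means$doses
  gh <- if (any(c("IC50", "Slope") %in% methods)) hill_grid(doses) else NULL
  stats_mat <- matrix(NA_real_, n_null, length(methods),
                      dimnames = list(NULL, methods))
  set.seed(seed + 104729L)  # disjoint from the alternative stream
  for (r in seq_len(n_null)) {
    sim <- simulate_dr(config, seed = NULL)
    stats_mat[r, ] <- method_statistics(doses, sim$Y, sim$genotype_counts,
                                        methods, gh)
  }
  structure(list(statistics = stats_mat, methods = methods, n_null = n_null,
                 fingerprint = config_fingerprint(config)),
            class = "null_reference")
}

#' Empirical (resampling) p-values against a null reference
#'
#' p = (1 + #\{null >= stat\}) / (1 + N_null); the add-one convention keeps
#' every p-value positive, and ties between an observed and a null statistic
#' count toward the null exceedances (conservative).
#'
#' @param alt_stats vector of observed statistics (larger = more extreme).
#' @param null_ref a [null_reference()] (or a plain numeric vector of null
#'   statistics).
#' @param method method column of the reference to compare against.
#' @param fingerprint optional generating-model fingerprint of the
#'   alternative stream; must match the reference when both are given.
#' @return vector of p-values in (0, 1].
#' @export
empirical_pvalues <- function(alt_stats, null_ref, method = NULL,
                              fingerprint = NULL) {
  if (inherits(null_ref, "null_reference")) {
    if (!is.null(fingerprint) && !identical(fingerprint, null_ref$fingerprint))
      stop("alternative and null streams come from different generating models")
    if (is.null(method)) {
      if (ncol(null_ref$statistics) != 1L)
        stop("method must be named when the reference holds several methods")
      method <- null_ref$methods[1L]
    }
    nulls <- null_ref$statistics[, method]
  } else nulls <- as.numeric(null_ref)
  nulls <- nulls[is.finite(nulls)]
  N <- length(nulls)
  if (!N) stop("empty null reference")
  ## #(null >= x) via one sort of the nulls
  srt <- sort(nulls)
  n_less <- findInterval(alt_stats, srt, left.open = TRUE)  # #{null < x}
  (1 + (N - n_less)) / (1 + N)
}

#' Rejection proportion and its Monte-Carlo standard error
#'
#' @param pvals vector of p-values in (0, 1].
#' @param alpha significance level.
#' @return list with `power` and `mc_stderr` = sqrt(power(1-power)/n).
#' @export
estimate_power <- function(pvals, alpha = 0.05) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no p-values")
  pw <- mean(pvals <= alpha)
  list(power = pw, mc_stderr = sqrt(pw * (1 - pw) / length(pvals)),
       n_reps = length(pvals))
}

#' Power comparison experiment over an effect-size grid
#'
#' For each effect size, `n_alt` datasets are simulated and every method is
#' evaluated on the same dataset (paired design).  P-values are either
#' empirical against a per-method null reference built once from the ES = 0
#' stream (`pvalue_mode = "resampling"`, as required when the pooled ANOVA is
#' in play) or asymptotic.
#'
#' @param config a [simulation_config()]; its `effect_size` is ignored.
#' @param methods methods to compare.
#' @param effect_sizes numeric grid.
#' @param n_alt datasets per effect size.
#' @param n_null null datasets for the resampling reference.
#' @param alpha significance level.
#' @param seed integer seed; alternative and null streams use disjoint
#'   offsets.
#' @param pvalue_mode `"resampling"` or `"asymptotic"`.
#' @return object of class `power_experiment`: list with `table` (data.frame
#'   method, effect_size, power, mc_stderr, n_reps), `pvalues` (per effect
#'   size an n_alt x methods matrix) and the settings.
#' @export
run_power_experiment <- function(config, methods = MVGWAS_METHODS,
                                 effect_sizes = c(0, 0.25, 0.5, 0.75, 1),
                                 n_alt = 2500L, n_null = 10000L, alpha = 0.05,
                                 seed = 1L,
                                 pvalue_mode = c("resampling", "asymptotic")) {
  pvalue_mode <- match.arg(pvalue_mode)
  stopifnot(all(methods %in% MVGWAS_METHODS))
  doses <- config$means$doses
  gh <- if (any(c("IC50", "Slope") %in% methods)) hill_grid(doses) else NULL
  nref <- if (pvalue_mode == "resampling")
    null_reference(config, methods, n_null = n_null, seed = seed) else NULL

  rows <- list()
  pmats <- list()
  for (es in effect_sizes) {
    cfg <- config
    cfg$effect_size <- es
    stats_mat <- matrix(NA_real_, n_alt, length(methods),
                        dimnames = list(NULL, methods))
    pmat_asym <- stats_mat
    set.seed(seed + round(1e6 * es))
    for (r in seq_len(n_alt)) {
      sim <- simulate_dr(cfg, seed = NULL)
      st <- method_statistics(doses, sim$Y, sim$genotype_counts, methods, gh)
      stats_mat[r, ] <- st
      pmat_asym[r, ] <- attr(st, "p_asymptotic")
    }
    fail_frac <- colMeans(is.na(stats_mat))
    if (any(fail_frac > 0.2))
      stop("method(s) failing on > 20% of replicates: ",
           paste(methods[fail_frac > 0.2], collapse = ", "))
    pmat <- if (pvalue_mode == "resampling") {
      out <- stats_mat
      for (m in methods) out[, m] <- empirical_pvalues(stats_mat[, m], nref, m)
      out[is.na(stats_mat)] <- NA
      out
    } else pmat_asym
    pmats[[as.character(es)]] <- pmat
    for (m in methods) {
      pw <- estimate_power(pmat[, m], alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, effect_size = es, power = pw$power,
        mc_stderr = pw$mc_stderr, n_reps = pw$n_reps)
    }
  }
  structure(list(table = do.call(rbind, rows), pvalues = pmats,
                 methods = methods, alpha = alpha, seed = seed,
                 pvalue_mode = pvalue_mode, null_reference = nref),
            class = "power_experiment")
}

#' Friedman rank test across methods
#'
#' Ranks the methods' p-values within each replicate (average ranks on ties)
#' and tests for systematic differences between methods.
#'
#' @param pmatrix replicates x methods matrix of p-values.
#' @return list with `statistic` (Friedman chi-square), `df`, `p_value`.
#' @export
friedman_compare <- function(pmatrix) {
  pmatrix <- as.matrix(pmatrix)
  if (ncol(pmatrix) < 2L) stop("need at least 2 methods")
  pmatrix <- pmatrix[stats::complete.cases(pmatrix), , drop = FALSE]
  if (nrow(pmatrix) < 2L) stop("need at least 2 complete replicates")
  if (all(apply(pmatrix, 1L, function(r) length(unique(r)) == 1L)))
    return(list(statistic = 0, df = ncol(pmatrix) - 1L, p_value = 1))
  ft <- stats::friedman.test(pmatrix)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value)
}

#' Type-I error of one method under a null generating model
#'
#' @param method one of `r toString(MVGWAS_METHODS)`.
#' @param null_config a [simulation_config()] with `effect_size = 0`.
#' @param n_reps number of null datasets.
#' @param alpha significance level.
#' @param mode `"asymptotic"` (the method's own p-values) or `"resampling"`
#'   (empirical p-values against a second, independent null stream).
#' @param seed integer seed.
#' @param n_null resampling reference size (resampling mode only).
#' @return list with `rate`, `mc_stderr`, `n_reps`, plus the statistics and
#'   p-values used (for QQ diagnostics).
#' @export
type1_error <- function(method, null_config, n_reps = 2000L, alpha = 0.05,
                        mode = c("asymptotic", "resampling"), seed = 1L,
                        n_null = 2000L) {
  mode <- match.arg(mode)
  if (null_config$effect_size != 0)
    stop("type1_error requires a null configuration (effect_size = 0)")
  doses <- null_config$means$doses
  gh <- if (method %in% c("IC50", "Slope")) hill_grid(doses) else NULL
  stats_v <- p_v <- numeric(n_reps)
  dfs <- matrix(NA_real_, n_reps, 2L)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    sim <- simulate_dr(null_config, seed = NULL)
    st <- method_statistics(doses, sim$Y, sim$genotype_counts, method, gh)
    stats_v[r] <- st[[method]]
    p_v[r] <- attr(st, "p_asymptotic")[[method]]
  }
  if (mode == "resampling") {
    nref <- null_reference(null_config, method, n_null = n_null,
                           seed = seed + 1L)
    p_v <- empirical_pvalues(stats_v, nref, method)
  }
  pw <- estimate_power(p_v, alpha)
  list(rate = pw$power, mc_stderr = pw$mc_stderr, n_reps = pw$n_reps,
       statistics = stats_v, p_values = p_v, method = method, mode = mode)
}

#' QQ coordinates and a KS calibration test for null statistics
#'
#' Sorted observed statistics against theoretical quantiles at plotting
#' positions (i - 0.5)/N, plus a Kolmogorov-Smirnov test against the
#' reference distribution.
#'
#' @param null_stats vector of >= 100 statistics from null data.
#' @param reference `"F"` (requires `df1`, `df2`) or `"uniform"` (for
#'   p-values).
#' @param df1,df2 F reference degrees of freedom.
#' @return list with `points` (data.frame `theoretical`, `observed`),
#'   `ks_statistic`, `ks_p`.
#' @export
qq_data <- function(null_stats, reference = c("F", "uniform"),
                    df1 = NULL, df2 = NULL) {
  reference <- match.arg(reference)
  null_stats <- null_stats[is.finite(null_stats)]
  N <- length(null_stats)
  if (N < 100L) stop("need at least 100 statistics")
  pp <- (seq_len(N) - 0.5) / N
  theo <- switch(reference,
    F = {
      if (is.null(df1) || is.null(df2)) stop("F reference needs df1 and df2")
      stats::qf(pp, df1, df2)
    },
    uniform = pp)
  ks <- switch(reference,
    F = stats::ks.test(null_stats, stats::pf, df1 = df1, df2 = df2),
    uniform = stats::ks.test(null_stats, stats::punif))
  list(points = data.frame(theoretical = theo, observed = sort(null_stats)),
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
}
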