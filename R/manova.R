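# Per-SNP multivariate linear model: SSCP matrices, Pillai's trace, the F
# approximation, and the GWAS driver.

#' Specify the per-SNP design
#'
#' The genotypic model codes genotype as a 3-level factor via the indicators
#' I(g = 1) and I(g = 2), contributing 2 hypothesis df (1 df when only two
#' genotype classes are present); the additive model uses the minor-allele
#' count 0/1/2 as a single column.
#'
#' @param genetic_model `"genotypic"` (default) or `"additive"`.
#' @param covariate_columns names of covariate columns to adjust for;
#'   `NULL` uses all columns of the covariate matrix supplied downstream.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(genetic_model = c("genotypic", "additive"),
                        covariate_columns = NULL) {
  structure(list(genetic_model = match.arg(genetic_model),
                 covariate_columns = covariate_columns),
            class = "design_spec")
}

degenerate_error <- function(msg) {
  structure(class = c("mvgwas_degenerate", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Build full and reduced design matrices for one SNP
#'
#' @param genotype_counts vector of minor-allele counts in {0, 1, 2}
#'   (no missing values; subset before calling).
#' @param covariates optional numeric covariate matrix (already
#'   dummy-expanded), rows matching `genotype_counts`.
#' @param spec a [design_spec()].
#' @return list with `X_full`, `X_reduced` and `df_hyp`.  The reduced design
#'   is intercept + covariates; the full design adds the genotype columns.
#'   Under the genotypic model with only two observed genotype classes a
#'   single indicator is used and `df_hyp` is 1.  Collinear covariate columns
#'   are dropped by pivoted QR (tolerance 1e-8) from both designs.
#' @export
build_design <- function(genotype_counts, covariates = NULL, spec = design_spec()) {
  g <- genotype_counts
  if (anyNA(g)) stop("genotype_counts must not contain missing values")
  classes <- sort(unique(g))
  if (length(classes) < 2L)
    stop(degenerate_error("monomorphic SNP: fewer than 2 genotype classes"))
  n <- length(g)
  Xr <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates and genotypes differ in length")
    if (!is.null(spec$covariate_columns))
      covariates <- covariates[, spec$covariate_columns, drop = FALSE]
    Xr <- cbind(Xr, covariates)
    ## drop collinear covariate columns, keeping the intercept
    q <- qr(Xr, tol = 1e-8)
    if (q$rank < ncol(Xr)) {
      keep <- sort(q$pivot[seq_len(q$rank)])
      dropped <- colnames(Xr)[setdiff(seq_len(ncol(Xr)), keep)]
      message("dropping collinear covariate column(s): ",
              paste(dropped, collapse = ", "))
      Xr <- Xr[, keep, drop = FALSE]
    }
  }
  if (spec$genetic_model == "additive") {
    G <- matrix(as.numeric(g), n, 1L, dimnames = list(NULL, "g_add"))
  } else if (length(classes) == 3L) {
    G <- cbind(g1 = as.numeric(g == 1), g2 = as.numeric(g == 2))
  } else {
    ## two classes: one indicator for the larger count
    G <- matrix(as.numeric(g == classes[2L]), n, 1L, dimnames = list(NULL, "g1"))
  }
  list(X_full = cbind(Xr, G), X_reduced = Xr, df_hyp = ncol(G))
}

#' Hypothesis and error SSCP matrices for a multivariate linear model
#'
#' Fits the full and reduced models to the n x p response matrix by QR and
#' returns E (residual SSCP under the full model), H (extra SSCP explained
#' by the full model over the reduced one), and the degrees of freedom.
#'
#' @param Y n x p response matrix.
#' @param X_full,X_reduced design matrices; the column span of `X_reduced`
#'   must be contained in that of `X_full`.
#' @return object of class `sscp_pair`: list with `H`, `E`, `df_hyp`,
#'   `df_err`, `p`.
#' @export
fit_sscp <- function(Y, X_full, X_reduced) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  qf <- qr(X_full, tol = 1e-8)
  q0 <- qr(X_reduced, tol = 1e-8)
  if (qf$rank < ncol(X_full))
    stop("X_full is rank deficient after pruning")
  if (n <= qf$rank) stop("more model parameters than observations")
  E <- crossprod(qr.resid(qf, Y))
  H <- crossprod(qr.resid(q0, Y)) - E
  ## symmetrize against roundoff
  E <- (E + t(E)) / 2
  H <- (H + t(H)) / 2
  structure(list(H = H, E = E, df_hyp = qf$rank - q0$rank,
                 df_err = n - qf$rank, p = ncol(Y)),
            class = "sscp_pair")
}

#' Pillai's trace
#'
#' V = trace(H (H + E)^-1), computed through a symmetric Cholesky route and
#' clamped to [0, s] with s = min(p, df_hyp).
#'
#' @param sscp an [fit_sscp()] result (or a list with `H`, `E`, `df_hyp`, `p`).
#' @return the trace statistic V.
#' @export
pillai_trace <- function(sscp) {
  T_ <- sscp$H + sscp$E
  R <- tryCatch(chol(T_), error = function(e)
    stop("H + E is not positive definite: ", conditionMessage(e)))
  ## V = tr(R^-T H R^-1); solve triangular systems instead of inverting
  B <- backsolve(R, backsolve(R, sscp$H, transpose = TRUE))
  V <- sum(diag(B))
  s <- min(sscp$p, sscp$df_hyp)
  min(max(V, 0), s)
}

#' F approximation for Pillai's trace
#'
#' With s = min(p, df_hyp), m = (|p - df_hyp| - 1)/2 and
#' n* = (df_err - p - 1)/2,
#' \deqn{F = \frac{2n^* + s + 1}{2m + s + 1} \cdot \frac{V/s}{1 - V/s}}
#' on (s(2m + s + 1), s(2n* + s + 1)) degrees of freedom.  Exact when s = 1.
#'
#' @param V Pillai trace.
#' @param p number of responses.
#' @param df_hyp,df_err hypothesis and error degrees of freedom.
#' @return list with `F`, `df1`, `df2`, `p_value`, `note` (`""` normally;
#'   flags when V sits on the boundary and the p-value was floored).
#' @export
pillai_f_approx <- function(V, p, df_hyp, df_err) {
  if (df_err < p) stop("df_err must be at least p")
  s <- min(p, df_hyp)
  m <- (abs(p - df_hyp) - 1) / 2
  nstar <- (df_err - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nstar + s + 1)
  note <- ""
  if (V >= s - 1e-12) {
    ## perfect separation: V on its boundary
    return(list(F = Inf, df1 = df1, df2 = df2,
                p_value = .Machine$double.xmin, note = "boundary_statistic"))
  }
  Fst <- ((2 * nstar + s + 1) / (2 * m + s + 1)) * (V / s) / (1 - V / s)
  pv <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  if (pv == 0) { pv <- .Machine$double.xmin; note <- "p_floored" }
  list(F = Fst, df1 = df1, df2 = df2, p_value = pv, note = note)
}

## Lean Pillai p-value for simulation studies: genotypic 2-df test of g on Y,
## optional covariates.  Returns c(F, df1, df2, p).  No metadata overhead.
pillai_test_stat <- function(Y, g, covariates = NULL,
                             spec = design_spec()) {
  de <- build_design(g, covariates, spec)
  sscp <- fit_sscp(Y, de$X_full, de$X_reduced)
  V <- pillai_trace(sscp)
  fa <- pillai_f_approx(V, sscp$p, sscp$df_hyp, sscp$df_err)
  c(statistic = V, F = fa$F, df1 = fa$df1, df2 = fa$df2, p = fa$p_value)
}

empty_result <- function(snp, n_used, note) {
  data.frame(chr = snp$chromosome, snp = snp$snp_id, bp = snp$position,
             a1 = snp$minor_allele,
             a2 = setdiff(c(snp$allele1, snp$allele2), snp$minor_allele)[1],
             n_used = n_used, statistic = NA_real_, F = NA_real_,
             df1 = NA_integer_, df2 = NA_real_, p_value = NA_real_,
             note = note, stringsAsFactors = FALSE)
}

#' Test a single SNP
#'
#' Removes individuals with a missing genotype at this SNP, builds the
#' designs, and runs the Pillai pipeline.  Degenerate SNPs (monomorphic
#' after subsetting, or too few observations) yield a skipped row with a
#' note instead of an error.
#'
#' @param dataset an aligned [align_data()] result.
#' @param snp_index column index into the genotype count matrix.
#' @param spec a [design_spec()].
#' @return one-row data.frame (see [run_gwas()] for columns).
#' @export
test_snp <- function(dataset, snp_index, spec = design_spec()) {
  stopifnot(inherits(dataset, "mvgwas_dataset"))
  snp <- dataset$genotype$snps[snp_index, ]
  g <- dataset$genotype$counts[, snp_index]
  ok <- !is.na(g)
  n_used <- sum(ok)
  out <- tryCatch({
    Y <- dataset$phenotype$values[ok, , drop = FALSE]
    X <- if (is.null(dataset$covariates)) NULL else
      dataset$covariates$matrix[ok, , drop = FALSE]
    de <- build_design(g[ok], X, spec)
    sscp <- fit_sscp(Y, de$X_full, de$X_reduced)
    V <- pillai_trace(sscp)
    fa <- pillai_f_approx(V, sscp$p, sscp$df_hyp, sscp$df_err)
    data.frame(chr = snp$chromosome, snp = snp$snp_id, bp = snp$position,
               a1 = snp$minor_allele,
               a2 = setdiff(c(snp$allele1, snp$allele2), snp$minor_allele)[1],
               n_used = n_used, statistic = V, F = fa$F, df1 = fa$df1,
               df2 = fa$df2, p_value = fa$p_value, note = fa$note,
               stringsAsFactors = FALSE)
  },
  mvgwas_degenerate = function(e) empty_result(snp, n_used, "monomorphic"),
  error = function(e) empty_result(snp, n_used, conditionMessage(e)))
  out
}

#' Run a MANOVA GWAS over every SNP
#'
#' Tests each SNP in `.bim` order with Pillai's trace.  The reduced-model
#' QR decomposition is shared across SNPs with complete genotypes; SNPs with
#' missing calls fall back to per-SNP complete-case analysis.
#'
#' @param dataset an aligned [align_data()] result.
#' @param spec a [design_spec()].
#' @param verbose log progress every `progress_every` SNPs.
#' @param progress_every integer.
#' @return data.frame of class `mvgwas_results`, one row per SNP: `chr`,
#'   `snp`, `bp`, `a1` (minor), `a2`, `n_used`, `statistic` (Pillai V), `F`,
#'   `df1`, `df2`, `p_value`, `note`.
#' @export
run_gwas <- function(dataset, spec = design_spec(), verbose = FALSE,
                     progress_every = 10000L) {
  stopifnot(inherits(dataset, "mvgwas_dataset"))
  m <- ncol(dataset$genotype$counts)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    rows[[j]] <- test_snp(dataset, j, spec)
    if (verbose && j %% progress_every == 0L)
      message("tested ", j, " / ", m, " SNPs")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mvgwas_results", "data.frame")
  out
}
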