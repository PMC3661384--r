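# Delimited phenotype / covariate tables keyed by (FID, IID), dummy coding,
# sample alignment, and the results writer.

read_keyed_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 3L) stop("expected at least FID, IID and one data column in ", path)
  names(tab)[1:2] <- c("FID", "IID")
  key <- paste(tab$FID, tab$IID)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (FID, IID) pair in ", path, ": ", dup)
  }
  tab
}

#' Read a phenotype table
#'
#' Whitespace/tab-delimited with a header; first two columns are FID and IID,
#' remaining columns are the responses at each of the d concentrations.  All
#' phenotype cells must be numeric; blanks / NA mark missing responses.
#'
#' @param path file path.
#' @param doses optional vector of the d concentrations (ascending).  Dose
#'   values are study metadata, not inferred from column names; the default
#'   is the equally spaced grid `1..d`.
#' @return object of class `mvgwas_phenotypes`: list with `samples`
#'   (data.frame `fid`, `iid`), `doses`, and the n x d `values` matrix.
#' @export
read_phenotype_table <- function(path, doses = NULL) {
  tab <- read_keyed_table(path)
  vals <- tab[, -(1:2), drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "NA" & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric phenotype value '%s' at row %d, column '%s' of %s",
                     v[bad[1]], bad[1], names(vals)[j], path))
      vals[[j]] <- num
    }
  }
  values <- as.matrix(vals)
  d <- ncol(values)
  if (d < 2L) stop("a multivariate phenotype needs d >= 2 response columns")
  if (is.null(doses)) doses <- seq_len(d)
  if (length(doses) != d) stop("length(doses) must match the number of response columns")
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be strictly increasing")
  structure(list(samples = data.frame(fid = tab$FID, iid = tab$IID,
                                      stringsAsFactors = FALSE),
                 doses = doses, values = values),
            class = "mvgwas_phenotypes")
}

#' Read a covariate table
#'
#' Same layout as [read_phenotype_table()].  Columns whose non-missing values
#' are all numeric are treated as numeric; any other column is nominal and is
#' expanded into 0/1 dummy columns against its first observed level.
#' Constant expanded columns are dropped.
#'
#' @param path file path.
#' @return object of class `mvgwas_covariates`: list with `samples`,
#'   `columns` (the raw columns with a `type` attribute) and `matrix`, the
#'   dummy-expanded numeric matrix used in model fitting.
#' @export
read_covariate_table <- function(path) {
  tab <- read_keyed_table(path)
  raw <- tab[, -(1:2), drop = FALSE]
  cols <- lapply(raw, function(v) {
    if (is.numeric(v)) return(structure(v, type = "numeric"))
    suppressWarnings(num <- as.numeric(v))
    if (all(is.na(num) == (is.na(v) | v == "NA")))
      structure(num, type = "numeric")
    else structure(v, type = "nominal")
  })
  names(cols) <- names(raw)
  structure(list(samples = data.frame(fid = tab$FID, iid = tab$IID,
                                      stringsAsFactors = FALSE),
                 columns = cols,
                 matrix = expand_covariates(cols)),
            class = "mvgwas_covariates")
}

## dummy-code nominal columns (reference = first observed level) and drop
## constant expanded columns
expand_covariates <- function(cols) {
  out <- list()
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (attr(v, "type") == "numeric") {
      out[[nm]] <- as.numeric(v)
    } else {
      levs <- unique(v[!is.na(v)])
      for (lev in levs[-1L])
        out[[paste0(nm, "_", lev)]] <- as.numeric(v == lev)
    }
  }
  if (!length(out)) return(matrix(numeric(0), 0L, 0L))
  M <- do.call(cbind, out)
  keep <- apply(M, 2L, function(x) stats::sd(x, na.rm = TRUE) > 0)
  M[, keep, drop = FALSE]
}

#' Align genotypes, phenotypes and covariates on shared samples
#'
#' Restricts all components to the intersection of (FID, IID) keys, in
#' genotype order, and drops individuals with any missing phenotype value
#' (the MANOVA needs complete response vectors) or any missing covariate.
#' One message per drop reason reports the counts.
#'
#' @param genotype a [read_plink()] result.
#' @param phenotype a [read_phenotype_table()] result.
#' @param covariates optional [read_covariate_table()] result.
#' @return object of class `mvgwas_dataset` with aligned `genotype`,
#'   `phenotype`, `covariates` (or `NULL`) components and a `drops` attribute
#'   (named counts per drop reason).
#' @export
align_data <- function(genotype, phenotype, covariates = NULL) {
  gk <- paste(genotype$samples$fid, genotype$samples$iid)
  pk <- paste(phenotype$samples$fid, phenotype$samples$iid)
  common <- intersect(gk, pk)
  ck <- NULL
  if (!is.null(covariates)) {
    ck <- paste(covariates$samples$fid, covariates$samples$iid)
    common <- intersect(common, ck)
  }
  n_input <- length(unique(c(gk, pk, ck)))
  drops <- c(not_shared = n_input - length(common))
  if (!length(common)) stop("no samples shared across genotype/phenotype/covariate inputs")

  pi_ <- match(common, pk)
  incomplete <- rowSums(is.na(phenotype$values[pi_, , drop = FALSE])) > 0
  drops["missing_phenotype"] <- sum(incomplete)
  common <- common[!incomplete]
  if (!is.null(covariates)) {
    ci <- match(common, ck)
    miss_cov <- rowSums(is.na(covariates$matrix[ci, , drop = FALSE])) > 0
    drops["missing_covariate"] <- sum(miss_cov)
    common <- common[!miss_cov]
  }
  if (!length(common)) stop("no samples left after complete-case filtering")
  ## final order follows the genotype file
  common <- common[order(match(common, gk))]

  gi <- match(common, gk)
  genotype$samples <- genotype$samples[gi, , drop = FALSE]
  genotype$counts <- genotype$counts[gi, , drop = FALSE]
  pi_ <- match(common, pk)
  phenotype$samples <- phenotype$samples[pi_, , drop = FALSE]
  phenotype$values <- phenotype$values[pi_, , drop = FALSE]
  if (!is.null(covariates)) {
    ci <- match(common, ck)
    covariates$samples <- covariates$samples[ci, , drop = FALSE]
    covariates$matrix <- covariates$matrix[ci, , drop = FALSE]
    covariates$columns <- lapply(covariates$columns, function(v) {
      a <- attr(v, "type"); v <- v[ci]; attr(v, "type") <- a; v
    })
  }
  for (r in names(drops))
    if (drops[[r]] > 0)
      message("align_data: dropped ", drops[[r]], " sample(s), reason: ", r)
  structure(list(genotype = genotype, phenotype = phenotype,
                 covariates = covariates),
            class = "mvgwas_dataset", drops = drops)
}

#' @export
print.mvgwas_dataset <- function(x, ...) {
  cat(sprintf("aligned dataset: %d individuals, %d SNPs, %d responses%s\n",
              nrow(x$genotype$counts), ncol(x$genotype$counts),
              ncol(x$phenotype$values),
              if (is.null(x$covariates)) "" else
                sprintf(", %d covariate columns", ncol(x$covariates$matrix))))
  invisible(x)
}

#' Write per-SNP association results
#'
#' Tab-delimited with header
#' `CHR SNP BP A1 A2 N STAT F DF1 DF2 P NOTE`; A1 is the minor allele, STAT
#' the method statistic (Pillai's V for MANOVA), and p-values are printed in
#' scientific notation with 6 significant digits after the decimal so that
#' genome-wide p-values never collapse to 0.  Skipped SNPs keep their row
#' with NA fields and an explanatory NOTE.
#'
#' @param results a [run_gwas()] result (non-empty).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  if (!nrow(results)) stop("no results to write")
  fmt_p <- function(p) ifelse(is.na(p), "NA",
                              trimws(formatC(p, format = "e", digits = 6)))
  fmt_n <- function(x, digits = 6) ifelse(is.na(x), "NA",
                                          trimws(formatC(x, format = "g",
                                                         digits = digits)))
  out <- data.frame(CHR = results$chr, SNP = results$snp, BP = results$bp,
                    A1 = results$a1, A2 = results$a2, N = results$n_used,
                    STAT = fmt_n(results$statistic), F = fmt_n(results$F),
                    DF1 = ifelse(is.na(results$df1), "NA", results$df1),
                    DF2 = fmt_n(results$df2), P = fmt_p(results$p_value),
                    NOTE = ifelse(results$note == "", ".", results$note))
  ok <- tryCatch({
    utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
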