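# Four-parameter logistic (hill) dose-response curves: evaluation, fast
# batched least-squares fitting, and empirical AUC.

#' Evaluate a four-parameter logistic (hill) curve
#'
#' The parameterization is
#' \deqn{y = Min + (Max - Min) / (1 + 10^{slope (\log_{10} dose - \log_{10} IC50)})}
#' so that with a positive slope the response decreases from `max` toward
#' `min` as dose increases (the usual shape of a viability curve).
#'
#' @param dose vector of positive concentrations.
#' @param min,max lower and upper asymptotes, in response units.
#' @param ic50 dose of half-maximal response (same units as `dose`, > 0).
#' @param slope unitless hill slope; positive for a decreasing curve.
#' @return numeric vector of responses.
#' @export
hill_response <- function(dose, min, max, ic50, slope) {
  stopifnot(all(dose > 0), ic50 > 0)
  min + (max - min) / (1 + 10^(slope * (log10(dose) - log10(ic50))))
}

## Precompute orthonormal bases [1, f(b, c)] for a coarse (slope, log10 IC50)
## grid over a fixed dose grid.  Grid points where f is numerically constant
## (degenerate basis) are dropped so they cannot win the projection contest
## with an arbitrary second direction.
hill_grid <- function(doses, n_slope = 13L, n_ic50 = 13L) {
  ld <- log10(doses)
  bs <- seq(-6, 6, length.out = n_slope)
  cs <- seq(min(ld) - 0.6, max(ld) + 0.6, length.out = n_ic50)
  grid <- expand.grid(b = bs, c = cs)
  keep <- rep(TRUE, nrow(grid))
  Qs <- matrix(0, length(ld), 2L * nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- 1 / (1 + 10^(grid$b[i] * (ld - grid$c[i])))
    if (stats::sd(f) < 1e-3) { keep[i] <- FALSE; next }
    Qs[, (2L * i - 1L):(2L * i)] <- qr.Q(qr(cbind(1, f)))
  }
  list(ld = ld, grid = grid[keep, ], Qs = Qs[, rep(keep, each = 2L)])
}

## Batched solve of n symmetric positive-definite 4x4 systems by unrolled
## Cholesky; every input is an n-vector.  Returns an n x 4 step matrix; rows
## that fail (non-PD after damping) come back all-zero.
solve4_batch <- function(A, g) {
  eps <- 1e-12
  l11 <- sqrt(pmax(A[[1]], eps))
  l21 <- A[[2]] / l11; l31 <- A[[3]] / l11; l41 <- A[[4]] / l11
  l22 <- sqrt(pmax(A[[5]] - l21^2, eps))
  l32 <- (A[[6]] - l31 * l21) / l22
  l42 <- (A[[7]] - l41 * l21) / l22
  l33 <- sqrt(pmax(A[[8]] - l31^2 - l32^2, eps))
  l43 <- (A[[9]] - l41 * l31 - l42 * l32) / l33
  l44 <- sqrt(pmax(A[[10]] - l41^2 - l42^2 - l43^2, eps))
  ## forward substitution L z = g
  z1 <- g[[1]] / l11
  z2 <- (g[[2]] - l21 * z1) / l22
  z3 <- (g[[3]] - l31 * z1 - l32 * z2) / l33
  z4 <- (g[[4]] - l41 * z1 - l42 * z2 - l43 * z3) / l44
  ## back substitution L' x = z
  x4 <- z4 / l44
  x3 <- (z3 - l43 * x4) / l33
  x2 <- (z2 - l32 * x3 - l42 * x4) / l22
  x1 <- (z1 - l21 * x2 - l31 * x3 - l41 * x4) / l11
  out <- cbind(x1, x2, x3, x4)
  out[!is.finite(rowSums(out)), ] <- 0
  out
}

## Core batched fitter: coarse-grid start + Levenberg-Marquardt over
## (a, b2, slope, log10 IC50) with the model y = a + b2 * f.
## Y is n x d; one fit per row.  Deterministic.
fit_hill_engine <- function(doses, Y, max_iter = 12L, grid = NULL) {
  ld <- log10(doses)
  d <- length(ld)
  n <- nrow(Y)
  if (is.null(grid)) grid <- hill_grid(doses)
  ss_y <- rowSums(Y^2)

  ## stage 1: best coarse grid cell per row by projection onto [1, f]
  P <- (Y %*% grid$Qs)^2
  pr <- P[, seq(1L, ncol(P), 2L), drop = FALSE] + P[, seq(2L, ncol(P), 2L), drop = FALSE]
  best <- max.col(pr, ties.method = "first")
  b <- grid$grid$b[best]
  lc <- grid$grid$c[best]

  logistic_rows <- function(b, lc) 1 / (1 + exp(log(10) * (outer(b, ld) - b * lc)))
  lin_fit <- function(F) {
    fm <- rowMeans(F); ym <- rowMeans(Y)
    sxx <- rowSums((F - fm)^2)
    b2 <- rowSums((F - fm) * Y) / pmax(sxx, 1e-12)
    a <- ym - b2 * fm
    list(a = a, b2 = b2, sse = rowSums((Y - a - b2 * F)^2))
  }
  st <- lin_fit(logistic_rows(b, lc))
  a <- st$a; b2 <- st$b2; sse <- st$sse

  ## stage 2: damped Gauss-Newton, all rows at once
  lam <- rep(1e-3, n)
  improved <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    F <- logistic_rows(b, lc)
    FF <- F * (1 - F)
    Jb <- -b2 * log(10) * (outer(rep(1, n), ld) - lc) * FF
    Jl <- b2 * log(10) * b * FF
    r <- Y - a - b2 * F
    g <- list(rowSums(r), rowSums(r * F), rowSums(r * Jb), rowSums(r * Jl))
    A <- list(rep(d, n), rowSums(F), rowSums(Jb), rowSums(Jl),
              rowSums(F^2), rowSums(F * Jb), rowSums(F * Jl),
              rowSums(Jb^2), rowSums(Jb * Jl), rowSums(Jl^2))
    A[[1]] <- A[[1]] * (1 + lam); A[[5]] <- A[[5]] * (1 + lam) + 1e-12
    A[[8]] <- A[[8]] * (1 + lam) + 1e-12; A[[10]] <- A[[10]] * (1 + lam) + 1e-12
    step <- solve4_batch(A, g)
    an <- a + step[, 1]; b2n <- b2 + step[, 2]
    bn <- pmin(pmax(b + step[, 3], -15), 15)
    lcn <- pmin(pmax(lc + step[, 4], min(ld) - 3), max(ld) + 3)
    ssen <- rowSums((Y - an - b2n * logistic_rows(bn, lcn))^2)
    acc <- is.finite(ssen) & ssen < sse
    a[acc] <- an[acc]; b2[acc] <- b2n[acc]; b[acc] <- bn[acc]; lc[acc] <- lcn[acc]
    improved <- acc & (sse - ssen > 1e-12 * (sse + 1e-12))
    sse[acc] <- ssen[acc]
    lam[acc] <- pmax(lam[acc] / 3, 1e-9)
    lam[!acc] <- pmin(lam[!acc] * 9, 1e7)
    if (!any(improved)) break
  }

  ## canonical form: Max > Min (the 4PL is invariant under
  ## (Min, Max, slope) -> (Max, Min, -slope))
  neg <- b2 < 0
  min_a <- ifelse(neg, a + b2, a)
  max_a <- ifelse(neg, a, a + b2)
  slope <- ifelse(neg, -b, b)
  ic50 <- 10^lc
  converged <- (max_a - min_a) > 1e-8 &
    abs(slope) > 1e-3 & abs(slope) < 14.9 &
    ic50 >= min(doses) / 100 & ic50 <= max(doses) * 100
  list(min = min_a, max = max_a, ic50 = ic50, log_ic50 = lc,
       slope = slope, rss = pmax(sse, 0), converged = converged)
}

#' Fit a four-parameter logistic curve to one dose-response profile
#'
#' Least-squares fit of the hill equation (see [hill_response()]) by a
#' deterministic multi-start: a coarse grid over (slope, log10 IC50) with the
#' two linear parameters profiled out, followed by damped Gauss-Newton
#' refinement of all four parameters.  The fit is reported in canonical form
#' with `max_asymptote > min_asymptote`; a decreasing viability curve has a
#' positive slope.
#'
#' @param doses vector of d >= 4 positive concentrations.
#' @param responses numeric vector of length d.
#' @param max_iter maximum Gauss-Newton iterations.
#' @return object of class `hill_fit`: a list with `min_asymptote`,
#'   `max_asymptote`, `ic50`, `slope`, `converged`, `rss`.  `converged` is
#'   `FALSE` for degenerate curves (e.g. constant response, slope pinned at
#'   its bound, or IC50 outside `[min(doses)/100, max(doses)*100]`).
#' @examples
#' d <- c(0.5, 1, 2, 4, 8, 16)
#' y <- hill_response(d, min = 0.1, max = 1, ic50 = 2, slope = 1.5)
#' fit_hill(d, y)
#' @export
fit_hill <- function(doses, responses, max_iter = 60L) {
  if (length(doses) < 4L) stop("at least 4 doses are required to fit a 4-parameter curve")
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(responses) != length(doses)) stop("doses and responses differ in length")
  if (anyNA(responses)) stop("responses contain missing values")
  if (stats::sd(responses) == 0) {
    out <- list(min_asymptote = responses[1], max_asymptote = responses[1],
                ic50 = NA_real_, slope = NA_real_, converged = FALSE, rss = 0)
    class(out) <- "hill_fit"
    return(out)
  }
  fit <- fit_hill_engine(doses, matrix(responses, nrow = 1L), max_iter = max_iter,
                         grid = hill_grid(doses, n_slope = 25L, n_ic50 = 25L))
  out <- list(min_asymptote = fit$min, max_asymptote = fit$max, ic50 = fit$ic50,
              slope = fit$slope, converged = fit$converged, rss = fit$rss)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("4PL fit: Min %.4g  Max %.4g  IC50 %.4g  Slope %.4g  (rss %.3g, %s)\n",
              x$min_asymptote, x$max_asymptote, x$ic50, x$slope, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit hill curves to every row of a response matrix
#'
#' Batched version of [fit_hill()] sharing one dose grid, used by the
#' summary-based association methods and the simulation studies.
#'
#' @param doses vector of d >= 4 positive concentrations.
#' @param Y n x d response matrix, one curve per row.
#' @param max_iter Gauss-Newton iterations.
#' @param grid optional precomputed starting grid (from repeated calls on the
#'   same dose grid); built automatically when `NULL`.
#' @return data.frame with columns `min`, `max`, `ic50`, `log_ic50`, `slope`,
#'   `rss`, `converged`, one row per curve.
#' @export
fit_hill_curves <- function(doses, Y, max_iter = 12L, grid = NULL) {
  if (length(doses) < 4L) stop("at least 4 doses are required to fit a 4-parameter curve")
  if (any(doses <= 0)) stop("doses must be positive")
  Y <- as.matrix(Y)
  if (ncol(Y) != length(doses)) stop("ncol(Y) must equal length(doses)")
  fit <- fit_hill_engine(doses, Y, max_iter = max_iter, grid = grid)
  ## constant rows are never identifiable
  const <- apply(Y, 1L, function(y) stats::sd(y) == 0)
  fit$converged[const] <- FALSE
  data.frame(min = fit$min, max = fit$max, ic50 = fit$ic50,
             log_ic50 = fit$log_ic50, slope = fit$slope, rss = fit$rss,
             converged = fit$converged)
}

#' Empirical area under a dose-response curve
#'
#' Trapezoid-rule integral of the responses over the dose grid as given
#' (or over log10 dose with `log_dose = TRUE`).
#'
#' @param doses ascending vector of d >= 2 concentrations.
#' @param responses numeric vector of length d, or an n x d matrix (one curve
#'   per row).
#' @param log_dose integrate over log10(dose) instead of raw dose.
#' @return a number, or a vector of length n for matrix input.
#' @examples
#' auc_empirical(1:6, rep(1, 6))   # 5
#' auc_empirical(c(0, 1), c(1, 0)) # 0.5
#' @export
auc_empirical <- function(doses, responses, log_dose = FALSE) {
  if (length(doses) < 2L) stop("need at least 2 doses")
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be strictly increasing")
  x <- if (log_dose) log10(doses) else doses
  w <- diff(x) / 2
  if (is.matrix(responses)) {
    if (ncol(responses) != length(doses)) stop("ncol(responses) must equal length(doses)")
    as.vector((responses[, -ncol(responses), drop = FALSE] +
                 responses[, -1L, drop = FALSE]) %*% w)
  } else {
    if (length(responses) != length(doses)) stop("doses and responses differ in length")
    sum((responses[-length(responses)] + responses[-1L]) * w)
  }
}
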