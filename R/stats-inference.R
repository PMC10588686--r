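#' Principal component analysis with per-variable contributions
#'
#' Correlation-matrix PCA (variables standardized by default): eigenvalues,
#' percent variance per axis, loadings, per-variable contributions and
#' species scores. Axes are ordered by decreasing eigenvalue; the sign of
#' each axis is fixed so its largest-magnitude loading is positive.
#' Contributions are `100 * eigenvector^2`, summing to 100 per axis.
#'
#' @param X numeric species x variable matrix or data.frame (>= 2 rows and
#'   columns, no missing values).
#' @param standardize scale variables to unit variance (correlation PCA,
#'   the default) rather than covariance PCA.
#' @return object of class `pca_result`: `eigenvalues`,
#'   `percent_variance`, `cumulative_percent`, `loadings`, `contributions`,
#'   `scores`.
#' @export
pca <- function(X, standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2)
    stop_dominet("PCA needs at least 2 rows and 2 columns")
  if (any(!is.finite(X))) stop_dominet("PCA input contains missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_dominet("constant column(s): ",
                 paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X, center = TRUE, scale = standardize)
  C <- if (standardize) stats::cor(X) else stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (a in seq_len(ncol(vecs))) {       # sign convention
    top <- which.max(abs(vecs[, a]))
    if (vecs[top, a] < 0) vecs[, a] <- -vecs[, a]
  }
  axes <- paste0("PC", seq_along(vals))
  loadings <- sweep(vecs, 2, sqrt(vals), `*`)
  dimnames(loadings) <- list(colnames(X), axes)
  contributions <- 100 * vecs^2
  dimnames(contributions) <- list(colnames(X), axes)
  scores <- Z %*% vecs
  dimnames(scores) <- list(rownames(X), axes)
  pct <- 100 * vals / sum(vals)
  structure(
    list(eigenvalues = stats::setNames(vals, axes),
         percent_variance = stats::setNames(pct, axes),
         cumulative_percent = stats::setNames(cumsum(pct), axes),
         loadings = loadings, contributions = contributions,
         scores = scores, rotation = vecs, standardize = standardize),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", length(x$eigenvalues), "axes\n")
  print(round(rbind(eigenvalue = x$eigenvalues,
                    `% variance` = x$percent_variance,
                    `cumulative %` = x$cumulative_percent), 2))
  cat("Contributions (%):\n")
  print(round(x$contributions, 1))
  invisible(x)
}

#' Simple (optionally weighted) linear regression
#'
#' Ordinary or weighted least squares of `y` on a single predictor, with
#' the R-squared, F statistic (`df1 = 1`, `df2 = n - 2`) and two-sided
#' p-value from the F distribution. The field's convention of weighting by
#' the square root of each species' total interaction frequency is
#' available by passing those totals' square roots as `weights`.
#'
#' @param x predictor vector.
#' @param y response vector.
#' @param weights optional nonnegative case weights.
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `F`, `df1`, `df2`, `p_value`, `weights_used`, `n`.
#' @export
linreg <- function(x, y, weights = NULL) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(weights)) {
    weights <- weights[ok]
    if (any(weights < 0)) stop_dominet("weights must be nonnegative")
  }
  n <- length(x)
  if (n < 3 || length(y) != n)
    stop_dominet("need equal-length x and y with n >= 3")
  if (stats::sd(x) == 0) stop_dominet("zero variance in x")
  fit <- if (is.null(weights)) stats::lm(y ~ x)
         else stats::lm(y ~ x, weights = weights)
  sm <- summary(fit)
  r2 <- sm$r.squared
  df2 <- n - 2
  Fstat <- df2 * r2 / (1 - r2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, F = Fstat, df1 = 1L, df2 = df2,
         p_value = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
         weights_used = !is.null(weights), n = n),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "linreg: slope = %.4g, R2 = %.3f, F(%d,%d) = %.3f, p = %.4g%s\n",
    x$slope, x$r_squared, x$df1, x$df2, x$F, x$p_value,
    if (x$weights_used) " (weighted)" else ""))
  invisible(x)
}
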