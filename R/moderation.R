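# Empirical Bayes engine: rowwise least squares, variance-prior estimation by
# moment matching on the log scale, variance squeezing and moderated t.

#' Fit a linear model to every row of a matrix
#'
#' Ordinary least squares, feature by feature, under one common design matrix.
#' The heavy lifting is three matrix products, so 50,000 features fit in well
#' under a second.
#'
#' @param y numeric G x N matrix (features x samples).
#' @param design N x p design matrix of full column rank.
#' @return A list of class `row_lm` with components `coefficients` (G x p),
#'   `sigma2` (length-G residual variances RSS/(N-p)), `df_residual` (N - p),
#'   `cov_unscaled` ((X'X)^-1), `stdev_unscaled` (sqrt of its diagonal),
#'   `residuals` (G x N) and `hat` (leverages, length N).
#' @export
row_lm <- function(y, design) {
  y <- as.matrix(y)
  design <- as.matrix(design)
  N <- ncol(y); p <- ncol(design)
  if (nrow(design) != N)
    stop("design rows must equal the number of samples")
  qrd <- qr(design)
  if (qrd$rank < p) stop("design matrix is rank deficient")
  if (N <= p) stop("no residual degrees of freedom (N <= p)")
  cov_unscaled <- chol2inv(chol(crossprod(design)))
  coefficients <- y %*% design %*% cov_unscaled
  residuals <- y - coefficients %*% t(design)
  q <- qr.Q(qrd)
  structure(list(
    coefficients = coefficients,
    sigma2 = rowSums(residuals^2) / (N - p),
    df_residual = N - p,
    cov_unscaled = cov_unscaled,
    stdev_unscaled = sqrt(diag(cov_unscaled)),
    residuals = residuals,
    hat = rowSums(q * q)
  ), class = "row_lm")
}

#' Invert the trigamma function
#'
#' Solves psi'(x) = y for x > 0 by Newton iteration with the analytic
#' derivative psi''(x), started from the asymptotic inverse and safeguarded by
#' bisection. Used to recover the prior degrees of freedom from the spread of
#' log residual variances.
#'
#' @param y positive target value.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap before falling back to bisection.
#' @return x with trigamma(x) = y.
#' @export
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50L) {
  if (length(y) != 1L || !is.finite(y) || y <= 0)
    stop("'y' must be a single positive finite number")
  # tails: trigamma(x) ~ 1/x^2 (x -> 0), ~ 1/x (x -> Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    f <- trigamma(x) - y
    step <- f / psigamma(x, deriv = 2L)
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < tol * x) return(x_new)
    x <- x_new
  }
  # bisection fallback: trigamma is strictly decreasing
  lo <- 1e-8; hi <- 1e8
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi / lo < 1 + tol) break
  }
  sqrt(lo * hi)
}

#' Estimate the variance prior from an ensemble of residual variances
#'
#' Models the true feature variances as draws from a scaled inverse chi-square
#' prior with degrees of freedom `d0` and scale `s0_sq`, under which the
#' observed residual variances follow a scaled F distribution. Matching the
#' mean and variance of `log(sigma2)` (bias-corrected through digamma /
#' trigamma) yields closed-form moment equations; `d0` comes from inverting
#' the trigamma function. When the observed spread of log variances is no
#' larger than expected under a common variance, `d0 = Inf` and `s0_sq` is the
#' (bias-corrected) geometric mean.
#'
#' Features with zero residual variance carry no information about the prior
#' and are excluded from the moments (their count is reported); they are still
#' squeezed and tested downstream.
#'
#' @param sigma2 length-G vector of non-negative residual variances.
#' @param df residual degrees of freedom of each variance.
#' @return List with `d0`, `s0_sq`, and `n_zero` (features excluded).
#' @export
fit_var_prior <- function(sigma2, df) {
  if (df <= 0) stop("'df' must be positive")
  ok <- sigma2 > 0
  n_zero <- sum(!ok)
  if (!any(ok)) stop("all residual variances are zero: no variance information")
  e <- log(sigma2[ok]) - digamma(df / 2) + log(df / 2)
  m <- mean(e)
  if (sum(ok) < 2L)
    return(list(d0 = Inf, s0_sq = exp(m), n_zero = n_zero))
  v <- stats::var(e)  # unbiased: mean squared deviation times G/(G-1)
  excess <- v - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(m)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(m + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq, n_zero = n_zero)
}

#' Squeeze residual variances towards the prior
#'
#' Posterior variances are the precision-weighted convex combination
#' (d0 * s0_sq + df * sigma2) / (d0 + df); with an infinite-df prior every
#' feature gets `s0_sq`.
#'
#' @param sigma2 residual variances.
#' @param df their residual degrees of freedom.
#' @param d0,s0_sq prior degrees of freedom and prior variance, from
#'   [fit_var_prior].
#' @return Vector of posterior variances.
#' @export
squeeze_var <- function(sigma2, df, d0, s0_sq) {
  if (d0 < 0 || s0_sq <= 0) stop("invalid prior parameters")
  if (is.infinite(d0)) return(rep_len(s0_sq, length(sigma2)))
  (d0 * s0_sq + df * sigma2) / (d0 + df)
}

# Largest finite df used for t tail probabilities; t_1e6 is within 1e-9 of
# the normal, so an infinite-d0 prior needs no special casing.
MAX_DF <- 1e6

#' Moderated t-statistics for one contrast
#'
#' Replaces each feature's residual variance with its posterior (squeezed)
#' value in an ordinary t-statistic; under the prior the statistic is
#' t-distributed with d0 + df degrees of freedom, so shrinkage buys degrees
#' of freedom as well as stability.
#'
#' @param fit a [row_lm] fit.
#' @param d0,s0_sq prior parameters (see [fit_var_prior]).
#' @param contrast numeric contrast vector of length p, or a single column
#'   index.
#' @return List with `effect` (contrast estimates), `t`, `df_total`, `p`
#'   (two-sided), and `post_var`.
#' @export
moderated_t <- function(fit, d0, s0_sq, contrast) {
  p <- ncol(fit$coefficients)
  if (length(contrast) == 1L && contrast == round(contrast))
    contrast <- as.numeric(seq_len(p) == contrast)
  if (length(contrast) != p) stop("contrast length must equal ncol(design)")
  effect <- drop(fit$coefficients %*% contrast)
  su <- sqrt(drop(crossprod(contrast, fit$cov_unscaled %*% contrast)))
  post_var <- squeeze_var(fit$sigma2, fit$df_residual, d0, s0_sq)
  df_total <- min(fit$df_residual + d0, MAX_DF)
  se <- sqrt(post_var) * su
  t <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, Inf * sign(effect)))
  pval <- ifelse(se > 0 | effect == 0, 2 * stats::pt(-abs(t), df_total), 0)
  list(effect = effect, t = t, df_total = df_total, p = pval,
       post_var = post_var)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: sort ascending, take
#' q_(i) = min_{j >= i} p_(j) * G / j, cap at 1 and map back to input order.
#' Ties receive identical adjusted values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * n / seq.int(n, 1L)))
  q[order(o)]
}
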