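#' Convert methylated/unmethylated intensities to M values
#'
#' M = log2((meth + offset) / (unmeth + offset)). The offset (default 100,
#' the platform convention for 450k arrays) stabilises the log ratio when one
#' channel is near zero.
#'
#' @param meth,unmeth non-negative numeric matrices (or vectors) of methylated
#'   and unmethylated signal intensities, conformable.
#' @param offset non-negative stabilising offset added to both channels.
#' @return A [methyl_matrix] on the M scale (a plain numeric object if the
#'   inputs are not matrices).
#' @examples
#' intensities_to_m(300, 0)  # log2(400/100) = 2
#' @export
intensities_to_m <- function(meth, unmeth, offset = 100) {
  check_intensities(meth, unmeth, offset)
  m <- log2((meth + offset) / (unmeth + offset))
  if (is.matrix(meth) && ncol(meth) >= 2L) methyl_matrix(m, scale = "M") else m
}

#' Convert intensities to beta values
#'
#' beta = meth / (meth + unmeth + offset), the proportion of methylated
#' signal. The offset enters the denominator only; set `offset = 0` for the
#' plain ratio definition.
#'
#' @inheritParams intensities_to_m
#' @return A [methyl_matrix] on the beta scale (plain numeric for
#'   non-matrix input).
#' @examples
#' intensities_to_beta(900, 0)  # 0.9
#' @export
intensities_to_beta <- function(meth, unmeth, offset = 100) {
  check_intensities(meth, unmeth, offset)
  b <- meth / (meth + unmeth + offset)
  if (is.matrix(meth) && ncol(meth) >= 2L) methyl_matrix(b, scale = "beta") else b
}

check_intensities <- function(meth, unmeth, offset) {
  if (any(meth < 0) || any(unmeth < 0))
    stop("intensities must be non-negative")
  if (offset < 0)
    stop("offset must be non-negative")
  if (offset == 0 && (any(meth == 0) || any(unmeth == 0)))
    stop("offset must be positive when any intensity is zero")
  if (!identical(dim(meth), dim(unmeth)) || length(meth) != length(unmeth))
    stop("methylated and unmethylated matrices must be conformable")
  invisible(NULL)
}

#' Logit-transform beta values to M values
#'
#' M = log2(beta / (1 - beta)), the base-2 logit, so that the result agrees
#' with [intensities_to_m] in the offset-free limit. Values at exactly 0 or 1
#' (which the logit maps to infinity) are clamped to `eps` / `1 - eps` with a
#' warning; values outside \[0,1\] are an error.
#'
#' @param beta numeric matrix or vector of methylation proportions.
#' @param eps clamping bound for boundary values.
#' @return M values; a [methyl_matrix] if the input is one (or a matrix).
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2 0 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  v <- if (inherits(beta, "methyl_matrix")) as_plain_matrix(beta) else beta
  if (any(v < 0) || any(v > 1))
    stop("beta values must lie in [0, 1]")
  nb <- sum(v <= 0 | v >= 1)
  if (nb > 0L) {
    warning(sprintf("%d beta value(s) at 0 or 1 clamped to [%g, %g] before logit",
                    nb, eps, 1 - eps))
    v <- pmin(pmax(v, eps), 1 - eps)
  }
  m <- log2(v / (1 - v))
  if (is.matrix(v) && ncol(v) >= 2L) methyl_matrix(m, scale = "M") else m
}

#' Inverse-logit M values back to beta values
#'
#' beta = 2^M / (2^M + 1); the exact inverse of [beta_to_m] on (0, 1), used
#' for interpretation and plotting on the proportion scale.
#'
#' @param m numeric matrix or vector of M values.
#' @return beta values; a [methyl_matrix] if the input is a matrix.
#' @examples
#' m_to_beta(c(-2, 0, 2))  # 0.2 0.5 0.8
#' @export
m_to_beta <- function(m) {
  v <- if (inherits(m, "methyl_matrix")) as_plain_matrix(m) else m
  b <- stats::plogis(v * log(2))  # 2^m / (2^m + 1), overflow-safe
  if (is.matrix(v) && ncol(v) >= 2L) methyl_matrix(b, scale = "beta") else b
}

# Any input accepted by the fitting functions is brought to the M scale here;
# beta matrices are logit-transformed, M matrices pass through.
ensure_m_scale <- function(x) {
  if (inherits(x, "methyl_matrix") && methyl_scale(x) == "beta")
    return(beta_to_m(x))
  x
}
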