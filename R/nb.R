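#' Negative binomial parameters (failures convention)
#'
#' Parameter container for the negative binomial law of the number of
#' failures X before the r-th success, with success probability p:
#' \deqn{P(X = x) = \binom{x + r - 1}{r - 1} p^r (1-p)^x, \quad x = 0, 1, \dots}
#' so that \eqn{E(X) = r(1-p)/p} and \eqn{V(X) = r(1-p)/p^2 > E(X)}
#' (overdispersion). `r` may be any positive real (the binomial
#' coefficient generalizes through the gamma function); `p` must be in
#' (0, 1). This matches R's `size`/`prob` parameterization of
#' [stats::dnbinom()].
#'
#' @param r positive real success parameter.
#' @param p success probability in (0, 1).
#' @return an object of class `"nb_params"` with fields `r` and `p`.
#' @examples
#' nb_params(10, 0.5)
#' @export
nb_params <- function(r, p) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("r must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("p must be a single probability strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(r = r, p = p), class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  mom <- nb_moments(x)
  cat("negative binomial (failures before the r-th success): r = ",
      format(x$r), ", p = ", format(x$p), "\n", sep = "")
  cat("mean = ", format(mom[["mean"]]), ", variance = ",
      format(mom[["variance"]]), "\n", sep = "")
  invisible(x)
}

#' Negative binomial probability mass function
#'
#' @param params an [nb_params()].
#' @param x vector of non-negative integers.
#' @return P(X = x), evaluated in log space by [stats::dnbinom()].
#' @examples
#' nb_pmf(nb_params(2, 0.5), 1)  # 0.25
#' @export
nb_pmf <- function(params, x) {
  stopifnot(inherits(params, "nb_params"))
  if (any(x < 0) || any(x != floor(x))) {
    stop("x must contain non-negative integers", call. = FALSE)
  }
  stats::dnbinom(x, size = params$r, prob = params$p)
}

#' Mean and variance of a negative binomial law
#'
#' @param params an [nb_params()].
#' @return named numeric vector `c(mean, variance)` with
#'   mean = r(1-p)/p, variance = r(1-p)/p^2.
#' @examples
#' nb_moments(nb_params(10, 0.5))  # mean 10, variance 20
#' @export
nb_moments <- function(params) {
  stopifnot(inherits(params, "nb_params"))
  q <- 1 - params$p
  c(mean = params$r * q / params$p,
    variance = params$r * q / params$p^2)
}

#' Negative binomial quantile function
#'
#' Left-continuous generalized inverse: the smallest integer x with
#' CDF(x) >= u, as computed by [stats::qnbinom()]. This is the transform
#' that maps copula uniforms to counts.
#'
#' @param params an [nb_params()].
#' @param u probabilities strictly inside (0, 1).
#' @return non-negative integer quantiles.
#' @examples
#' nb_quantile(nb_params(1, 0.5), 0.5)  # 0: CDF(0) = 0.5 already
#' @export
nb_quantile <- function(params, u) {
  stopifnot(inherits(params, "nb_params"))
  if (any(u <= 0) || any(u >= 1)) {
    stop("u must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnbinom(u, size = params$r, prob = params$p)
}

#' Transform copula uniforms to negative binomial counts
#'
#' Applies [nb_quantile()] column by column. Because the quantile function
#' is monotone, within-column ordering of the uniforms is preserved and
#' rank dependence carries over to the counts (up to ties from
#' discreteness).
#'
#' @param u numeric matrix of uniforms in (0, 1), n x m.
#' @param params a single [nb_params()] (recycled over columns) or a list
#'   of m of them.
#' @return an n x m integer-valued count matrix.
#' @examples
#' u <- sample_copula(copula_spec("clayton", theta = 3, dim = 3), 100, seed = 1)
#' x <- counts_from_copula(u, nb_params(10, 0.5))
#' @export
counts_from_copula <- function(u, params) {
  if (!is.matrix(u)) u <- as.matrix(u)
  m <- ncol(u)
  if (inherits(params, "nb_params")) params <- rep(list(params), m)
  if (length(params) != m) {
    stop("need one nb_params per column of u", call. = FALSE)
  }
  x <- u
  for (j in seq_len(m)) {
    x[, j] <- nb_quantile(params[[j]], u[, j])
  }
  x
}

#' Normal-approximation Z-test on a sample mean
#'
#' Tests H0: mean = `null_mean` with the statistic
#' \deqn{Z = \frac{\bar X - \mu_0}{\sqrt{V_0/n}},}
#' where the null variance \eqn{V_0} is supplied (typically the
#' theoretical negative binomial variance r(1-p)/p^2 under the null), and
#' a two-sided p-value \eqn{2[1 - \Phi(|Z|)]}. `x` may be a vector (one
#' test) or a matrix (one test per column).
#'
#' @param x numeric vector, or matrix with variables in columns.
#' @param null_mean null mean(s), recycled over columns.
#' @param null_variance null variance(s) > 0, recycled over columns.
#' @return a data frame with one row per variable: `mean`, `z`, `p.value`.
#' @examples
#' set.seed(1)
#' x <- rnbinom(30, size = 10, prob = 0.5)
#' z_test(x, null_mean = 10, null_variance = 20)
#' @export
z_test <- function(x, null_mean, null_variance) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < 1L) stop("need at least one observation", call. = FALSE)
  if (any(null_variance <= 0)) {
    stop("null_variance must be positive", call. = FALSE)
  }
  xbar <- colMeans(x)
  z <- (xbar - null_mean) / sqrt(null_variance / n)
  data.frame(mean = xbar, z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Standardized skewness of the negative binomial sample mean
#'
#' The skewness of a single NB(r, p) count is
#' \eqn{\gamma = (2 - p)/\sqrt{(1-p)\,r}}; averaging n independent counts
#' divides it by \eqn{\sqrt n}, giving the standardized skewness
#' \eqn{\gamma/\sqrt n}. It quantifies how far the sampling distribution
#' of the mean is from symmetric, and hence how trustworthy the normal
#' approximation behind [z_test()] is: values near zero (about 0.05 or
#' below) indicate that individual p-values are close to uniform under
#' the null.
#'
#' @param params an [nb_params()].
#' @param n sample size >= 1.
#' @return the standardized skewness, a positive real decreasing in both
#'   r and n.
#' @examples
#' standardized_skewness(nb_params(5, 0.5), 30)   # about 0.17
#' standardized_skewness(nb_params(50, 0.5), 30)  # about 0.05
#' @export
standardized_skewness <- function(params, n) {
  stopifnot(inherits(params, "nb_params"))
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  gamma1 <- (2 - params$p) / sqrt((1 - params$p) * params$r)
  gamma1 / sqrt(n)
}
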