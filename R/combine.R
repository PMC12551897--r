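# p-values are clipped into [.p_eps, 1 - .p_eps] before the tangent/log
# transforms so that p = 0 or p = 1 never produces an infinite statistic.
.p_eps <- 1e-15

# crossover above which the Cauchy tail identity replaces the direct
# arctangent formula (the direct form loses all precision near p = 0)
.cct_crossover <- 1e8

.clip_p <- function(p) pmin(pmax(p, .p_eps), 1 - .p_eps)

#' Validate a vector of p-values and optional weights
#'
#' Checks the invariants shared by all combination tests: p-values must be
#' numeric, finite and inside \[0, 1\]; weights (if supplied) must be
#' non-negative, not all zero, and of the same length. Weights are
#' normalized to sum to one.
#'
#' @param p numeric vector of p-values, length m >= 1.
#' @param weights optional non-negative weights; `NULL` means equal weights.
#' @return a list with elements `p` (clipped to the open unit interval) and
#'   `weights` (normalized to sum to 1).
#' @keywords internal
validate_pvalues <- function(p, weights = NULL) {
  if (length(p) < 1L) stop("at least one p-value is required", call. = FALSE)
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p))) {
    stop("p-values must be finite numeric values", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (is.null(weights)) {
    weights <- rep.int(1 / m, m)
  } else {
    if (length(weights) != m) {
      stop("weights must have the same length as the p-values", call. = FALSE)
    }
    if (!is.numeric(weights) || anyNA(weights) || any(weights < 0)) {
      stop("weights must be non-negative numbers", call. = FALSE)
    }
    s <- sum(weights)
    if (s <= 0) stop("weights must not all be zero", call. = FALSE)
    weights <- weights / s
  }
  list(p = .clip_p(p), weights = weights)
}

# Global-null p-value of a Cauchy-distributed statistic. The direct form
# 0.5 - atan(psi)/pi cancels catastrophically for large |psi|; beyond the
# crossover we switch to the algebraically equivalent tail identity
# atan(1/psi)/pi (~ 1/(pi*psi) as psi -> Inf), and its mirror image for
# large negative psi.
.cauchy_tail_p <- function(psi, tail = abs(psi) > .cct_crossover) {
  ifelse(tail,
         ifelse(psi > 0, atan(1 / psi) / pi, 1 - atan(-1 / psi) / pi),
         0.5 - atan(psi) / pi)
}

.new_combination_result <- function(method, statistic, combined_p, m,
                                    weights, weights_used) {
  structure(
    list(method = method,
         statistic = statistic,
         combined_p = combined_p,
         m = m,
         weights = weights,
         weights_used = weights_used),
    class = "combination_result"
  )
}

#' Cauchy combination test (CCT)
#'
#' Combines m individual p-values into one global-null p-value through the
#' Cauchy transformation. Each p-value is mapped to
#' \eqn{\tan\{(0.5 - p_i)\pi\}}, which is standard Cauchy under a uniform
#' null; the test statistic is the weighted sum
#' \deqn{\Psi = \sum_{i=1}^m \omega_i \tan\{(0.5 - p_i)\pi\},}
#' with weights \eqn{\omega_i > 0} summing to one (equal by default). Because
#' the tail of a convex combination of Cauchy variables is itself
#' approximately standard Cauchy even under dependence, the combined
#' p-value is \eqn{0.5 - \arctan(\Psi)/\pi}, evaluated through a
#' numerically stable tail branch when \eqn{|\Psi|} is large.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param weights optional non-negative weights, normalized internally to
#'   sum to one; `NULL` (default) gives equal weights 1/m.
#' @return an object of class `"combination_result"` with elements
#'   `method`, `statistic`, `combined_p`, `m`, `weights`, `weights_used`.
#' @examples
#' cct_combine(c(0.78, 0.002, 0.74, 0.016, 0.89, 0.10))
#' @seealso [fisher_combine()], [minp_combine()], [combine_pvalues()]
#' @export
cct_combine <- function(p, weights = NULL) {
  v <- validate_pvalues(p, weights)
  psi <- sum(v$weights * tanpi(0.5 - v$p))
  .new_combination_result("cct", psi, .cauchy_tail_p(psi), length(v$p),
                          v$weights, weights_used = TRUE)
}

#' Fisher's combination test
#'
#' Combines m p-values through \eqn{\Psi = -2\sum_i \log p_i}, which under
#' independent uniform nulls follows a chi-square distribution with 2m
#' degrees of freedom; the combined p-value is its upper tail probability.
#' Weights are ignored (the statistic is defined unweighted); this is
#' recorded in the result's `weights_used` field.
#'
#' @inheritParams cct_combine
#' @return an object of class `"combination_result"`.
#' @examples
#' fisher_combine(c(0.78, 0.002, 0.74, 0.016, 0.89, 0.10))
#' @export
fisher_combine <- function(p, weights = NULL) {
  v <- validate_pvalues(p, weights)
  m <- length(v$p)
  stat <- -2 * sum(log(v$p))
  pc <- stats::pchisq(stat, df = 2 * m, lower.tail = FALSE)
  .new_combination_result("fisher", stat, pc, m, v$weights,
                          weights_used = FALSE)
}

#' Minimum p-value (MinP) test
#'
#' Rejects the global null on the smallest of the m p-values. Under
#' independent uniform nulls the minimum follows a Beta(1, m) law, so the
#' combined p-value is \eqn{1 - (1 - p_{(1)})^m} (the Sidak-type
#' adjustment). Weights are ignored.
#'
#' @inheritParams cct_combine
#' @return an object of class `"combination_result"`.
#' @examples
#' minp_combine(c(0.01, 0.5, 0.9))  # 1 - 0.99^3
#' @export
minp_combine <- function(p, weights = NULL) {
  v <- validate_pvalues(p, weights)
  m <- length(v$p)
  p1 <- min(v$p)
  # expm1/log1p form keeps precision when p1 is tiny
  pc <- -expm1(m * log1p(-p1))
  .new_combination_result("minp", p1, pc, m, v$weights,
                          weights_used = FALSE)
}

#' Combine p-values by one or all methods
#'
#' Dispatcher over [cct_combine()], [fisher_combine()] and
#' [minp_combine()].
#'
#' @inheritParams cct_combine
#' @param method one of `"cct"`, `"fisher"`, `"minp"`, or `"all"`.
#' @return for a single method, a `"combination_result"`; for `"all"`, a
#'   data frame with one row per method (columns `method`, `m`,
#'   `statistic`, `combined_p`).
#' @examples
#' combine_pvalues(c(0.94, 0.0015, 0.97, 0.79, 0.81), method = "all")
#' @export
combine_pvalues <- function(p, method = c("cct", "fisher", "minp", "all"),
                            weights = NULL) {
  method <- match.arg(method)
  if (method != "all") {
    fn <- switch(method, cct = cct_combine, fisher = fisher_combine,
                 minp = minp_combine)
    return(fn(p, weights))
  }
  res <- lapply(list(cct_combine, fisher_combine, minp_combine),
                function(f) f(p, weights))
  data.frame(
    method = vapply(res, `[[`, "", "method"),
    m = vapply(res, `[[`, 0L, "m"),
    statistic = vapply(res, `[[`, 0, "statistic"),
    combined_p = vapply(res, `[[`, 0, "combined_p"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.combination_result <- function(x, digits = 4, ...) {
  label <- switch(x$method,
                  cct = "Cauchy combination test",
                  fisher = "Fisher's combination test",
                  minp = "Minimum p-value (MinP) test")
  cat("\n\t", label, "\n\n", sep = "")
  cat("number of p-values combined: ", x$m, "\n", sep = "")
  stat_name <- switch(x$method, cct = "psi", fisher = "X-squared",
                      minp = "min(p)")
  cat(stat_name, " = ", format(x$statistic, digits = digits),
      ", combined p-value = ", format(x$combined_p, digits = digits),
      "\n", sep = "")
  if (!x$weights_used) {
    cat("(weights are not used by this method)\n")
  } else if (length(unique(x$weights)) > 1L) {
    cat("weights: ", paste(format(x$weights, digits = 3), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}
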