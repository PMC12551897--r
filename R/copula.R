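#' Specify an Archimedean copula
#'
#' Constructs a validated copula specification for the families used in the
#' count-data simulations: independence, Clayton (lower-tail dependence),
#' Gumbel-Hougaard (upper-tail dependence) and survival Clayton (the
#' copula of the componentwise complement of a Clayton vector, hence
#' upper-tail dependent). The dependence strength can be given either as
#' the copula parameter `theta` or as Kendall's `tau` (converted via
#' [tau_to_theta()]).
#'
#' Parameter ranges: Clayton and survival Clayton need `theta > 0`; Gumbel
#' needs `theta >= 1`, with `theta = 1` being exact independence.
#'
#' @param family `"independence"`, `"clayton"`, `"gumbel"` or
#'   `"survival_clayton"`.
#' @param theta copula dependence parameter (ignored for independence).
#' @param tau alternative to `theta`: Kendall's tau for the family.
#' @param dim dimension m >= 2 of the copula.
#' @return an object of class `"copula_spec"`.
#' @examples
#' copula_spec("clayton", theta = 3, dim = 10)
#' copula_spec("gumbel", tau = 0.5, dim = 2)   # theta = 2
#' @export
copula_spec <- function(family = c("independence", "clayton", "gumbel",
                                   "survival_clayton"),
                        theta = NULL, tau = NULL, dim = 2L) {
  family <- match.arg(family)
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 2L) stop("dim must be an integer >= 2", call. = FALSE)
  if (!is.null(tau)) {
    if (!is.null(theta)) {
      stop("supply either theta or tau, not both", call. = FALSE)
    }
    theta <- tau_to_theta(family, tau)
  }
  if (family == "independence") {
    theta <- NA_real_
  } else {
    if (is.null(theta) || !is.numeric(theta) || length(theta) != 1L ||
        !is.finite(theta)) {
      stop("theta must be a single finite number", call. = FALSE)
    }
    .check_theta(family, theta)
  }
  structure(list(family = family, theta = theta, dim = dim),
            class = "copula_spec")
}

.check_theta <- function(family, theta) {
  ok <- switch(family,
               independence = TRUE,
               clayton = theta > 0,
               survival_clayton = theta > 0,
               gumbel = theta >= 1)
  if (!ok) {
    rng <- switch(family, clayton = , survival_clayton = "theta > 0",
                  gumbel = "theta >= 1", independence = "")
    stop(sprintf("invalid theta = %g for the %s copula (requires %s)",
                 theta, family, rng), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.copula_spec <- function(x, ...) {
  cat("copula_spec: ", x$family, ", dim = ", x$dim, sep = "")
  if (!is.na(x$theta)) {
    cat(", theta = ", format(x$theta),
        " (Kendall's tau = ", format(theta_to_tau(x$family, x$theta), digits = 3),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Kendall's tau implied by a copula parameter
#'
#' Closed-form relations: Clayton (and survival Clayton)
#' \eqn{\tau = \theta/(\theta+2)}; Gumbel-Hougaard \eqn{\tau = 1 - 1/\theta};
#' independence 0.
#'
#' @param family copula family name as in [copula_spec()].
#' @param theta dependence parameter, valid for the family.
#' @return Kendall's tau.
#' @examples
#' theta_to_tau("clayton", 3)  # 0.6
#' theta_to_tau("gumbel", 5)   # 0.8
#' @export
theta_to_tau <- function(family, theta) {
  family <- match.arg(family, c("independence", "clayton", "gumbel",
                                "survival_clayton"))
  if (family == "independence") return(0)
  .check_theta(family, theta)
  switch(family,
         clayton = ,
         survival_clayton = theta / (theta + 2),
         gumbel = 1 - 1 / theta)
}

#' Copula parameter implied by Kendall's tau
#'
#' Inverse of [theta_to_tau()]: Clayton \eqn{\theta = 2\tau/(1-\tau)}
#' (requires tau in (0,1)); Gumbel \eqn{\theta = 1/(1-\tau)} (tau in
#' \[0,1)).
#'
#' @inheritParams theta_to_tau
#' @param tau Kendall's tau.
#' @return the dependence parameter theta.
#' @examples
#' tau_to_theta("clayton", 0.5)  # 2
#' tau_to_theta("gumbel", 0.5)   # 2
#' @export
tau_to_theta <- function(family, tau) {
  family <- match.arg(family, c("independence", "clayton", "gumbel",
                                "survival_clayton"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau)) {
    stop("tau must be a single finite number", call. = FALSE)
  }
  if (family == "independence") {
    if (tau != 0) stop("the independence copula has tau = 0", call. = FALSE)
    return(NA_real_)
  }
  if (family %in% c("clayton", "survival_clayton")) {
    if (tau <= 0 || tau >= 1) {
      stop("Clayton-type copulas require tau in (0, 1)", call. = FALSE)
    }
    return(2 * tau / (1 - tau))
  }
  if (tau < 0 || tau >= 1) {
    stop("the Gumbel-Hougaard copula requires tau in [0, 1)", call. = FALSE)
  }
  1 / (1 - tau)
}

# One-sided positive stable draw with Laplace transform exp(-t^alpha),
# alpha in (0, 1), by the Chambers-Mallows-Stuck representation.
.rstable_positive <- function(n, alpha) {
  theta <- stats::runif(n, 0, pi)
  w <- stats::rexp(n)
  (sin(alpha * theta) / sin(theta)^(1 / alpha)) *
    (sin((1 - alpha) * theta) / w)^((1 - alpha) / alpha)
}

# Marshall-Olkin frailty samplers. Each row shares one frailty draw V; the
# columns are psi(E_i / V) for the family's Archimedean generator psi.
.rclayton <- function(n, m, theta) {
  v <- stats::rgamma(n, shape = 1 / theta, rate = 1)
  e <- matrix(stats::rexp(n * m), n, m)
  (1 + e / v)^(-1 / theta)
}

.rgumbel <- function(n, m, theta) {
  if (theta == 1) {
    # the positive stable sampler is singular at alpha = 1; theta = 1 is
    # exact independence
    return(matrix(stats::runif(n * m), n, m))
  }
  v <- .rstable_positive(n, 1 / theta)
  e <- matrix(stats::rexp(n * m), n, m)
  exp(-(e / v)^(1 / theta))
}

# raw sampler shared by sample_copula() and the simulation engine; entries
# are nudged into the open unit interval so downstream quantile transforms
# never see 0 or 1
.copula_draw <- function(spec, n) {
  u <- switch(spec$family,
              independence = matrix(stats::runif(n * spec$dim), n, spec$dim),
              clayton = .rclayton(n, spec$dim, spec$theta),
              gumbel = .rgumbel(n, spec$dim, spec$theta),
              survival_clayton = 1 - .clip_p(.rclayton(n, spec$dim, spec$theta)))
  .clip_p(u)
}

#' Sample dependent uniforms from an Archimedean copula
#'
#' Draws n observations of an m-dimensional vector with Uniform(0,1)
#' margins and the dependence structure of `spec`. Clayton vectors use the
#' gamma-frailty (Marshall-Olkin) construction, Gumbel-Hougaard vectors a
#' positive-stable frailty via the Chambers-Mallows-Stuck sampler, and the
#' survival Clayton is the componentwise complement `1 - U` of a Clayton
#' draw. All entries are strictly inside (0, 1).
#'
#' @param spec a [copula_spec()].
#' @param n number of observations (rows).
#' @param seed optional integer; when given, the draw is reproducible
#'   (`set.seed(seed)` is applied first).
#' @return an n x m numeric matrix with columns `u1 ... um`.
#' @examples
#' u <- sample_copula(copula_spec("clayton", theta = 3, dim = 2), 1000, seed = 1)
#' cor(u[, 1], u[, 2], method = "kendall")  # about 0.6
#' @export
sample_copula <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "copula_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- .copula_draw(spec, n)
  colnames(u) <- paste0("u", seq_len(spec$dim))
  u
}

#' Empirical Kendall's tau between two columns of a sample
#'
#' Rank concordance between columns `i` and `j`, computed with
#' [stats::cor()] (`method = "kendall"`). Used as the distributional
#' oracle for the copula samplers.
#'
#' @param u numeric matrix with at least two rows.
#' @param i,j column indices (defaults 1 and 2).
#' @return Kendall's tau in \[-1, 1\].
#' @export
empirical_kendall_tau <- function(u, i = 1L, j = 2L) {
  if (nrow(u) < 2L) stop("need at least two observations", call. = FALSE)
  x <- u[, i]
  y <- u[, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Kendall's tau is undefined for a constant column", call. = FALSE)
  }
  stats::cor(x, y, method = "kendall")
}
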