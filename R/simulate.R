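# Monte Carlo drivers for the type-I-error, sensitivity, heatmap and
# sparse-signal power studies. All drivers share one vectorized engine:
# replicates are generated in blocks, each block laid out as a
# (B * n) x m matrix of observations whose B groups of n rows are the
# replicates, reduced to B x m sample means with rowsum().

# cap on the number of matrix entries held per block; keeps peak memory
# of the largest study (m = 500) modest without changing results
.block_budget <- 6e6

#' Simulation scenario configuration
#'
#' Bundles everything one Monte Carlo cell needs: the number of variables
#' m, the per-variable negative binomial success parameters (data
#' generating), the success probability p, the per-replicate sample size
#' n, the number of replicates M, the significance levels, the copula
#' driving cross-variable dependence (`NULL` = independence), the null
#' means the Z-tests are evaluated against, and the RNG seed. Scalars
#' `r` and `null_means` are broadcast to length m. When `null_means` is
#' omitted it defaults to the true means r(1-p)/p, i.e. an all-null
#' (type-I error) configuration. Null variances are always the
#' theoretical negative binomial variances implied by `null_means` and
#' `p` (the null law is fully specified, so the test uses its known
#' variance rather than a sample estimate).
#'
#' @param m number of variables (individual tests).
#' @param r success parameter(s); scalar or length-m vector.
#' @param p success probability, shared across variables.
#' @param n per-replicate sample size.
#' @param M number of Monte Carlo replicates.
#' @param alpha significance level(s) in (0, 1).
#' @param copula a [copula_spec()] with `dim = m`, or `NULL` for
#'   independent variables.
#' @param null_means null hypothesis mean(s); defaults to the true means.
#' @param seed optional integer seed.
#' @return an object of class `"scenario_config"`.
#' @examples
#' scenario_config(m = 10, r = 30, n = 30, M = 1000, seed = 1)
#' @export
scenario_config <- function(m, r, p = 0.5, n = 30, M = 10000,
                            alpha = c(0.05, 0.01), copula = NULL,
                            null_means = NULL, seed = NULL) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer", call. = FALSE)
  r_values <- rep_len(as.numeric(r), m)
  if (any(!is.finite(r_values)) || any(r_values <= 0)) {
    stop("all r values must be positive", call. = FALSE)
  }
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (n < 1 || M < 1) stop("n and M must be at least 1", call. = FALSE)
  if (any(alpha <= 0) || any(alpha >= 1)) {
    stop("all alpha levels must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(copula)) {
    stopifnot(inherits(copula, "copula_spec"))
    if (copula$dim != m) {
      stop("copula dimension must equal m", call. = FALSE)
    }
  }
  true_means <- r_values * (1 - p) / p
  if (is.null(null_means)) null_means <- true_means
  null_means <- rep_len(as.numeric(null_means), m)
  # null variance implied by the null mean at the shared p:
  # mean = r0(1-p)/p  =>  variance = mean / p
  null_vars <- null_means / p
  structure(
    list(m = m, r_values = r_values, p = p, n = as.integer(n),
         M = as.integer(M), alpha = sort(as.numeric(alpha)),
         copula = copula, null_means = null_means, null_vars = null_vars,
         true_means = true_means, seed = seed),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config: m = ", x$m, ", n = ", x$n, ", M = ", x$M,
      ", p = ", format(x$p), "\n", sep = "")
  cat("r: ", paste(format(unique(x$r_values)), collapse = ", "),
      if (length(unique(x$r_values)) < x$m) " (per variable)", "\n", sep = "")
  if (is.null(x$copula)) cat("dependence: independent variables\n")
  else cat("dependence: ", x$copula$family, " copula, theta = ",
           format(x$copula$theta), "\n", sep = "")
  cat("alpha: ", paste(format(x$alpha), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# one block of B replicates -> B x m matrix of individual two-sided
# Z-test p-values (clipped into the open unit interval)
.simulate_pvalue_block <- function(config, B) {
  n <- config$n
  m <- config$m
  rows <- B * n
  if (is.null(config$copula)) {
    u <- matrix(stats::runif(rows * m), rows, m)
  } else {
    spec <- config$copula
    spec$dim <- m
    u <- .copula_draw(spec, rows)
  }
  x <- u
  for (j in seq_len(m)) {
    x[, j] <- stats::qnbinom(u[, j], size = config$r_values[j],
                             prob = config$p)
  }
  xbar <- rowsum(x, rep(seq_len(B), each = n), reorder = FALSE) / n
  z <- sweep(xbar, 2L, config$null_means)
  z <- sweep(z, 2L, sqrt(config$null_vars / n), "/")
  .clip_p(2 * stats::pnorm(-abs(z)))
}

# B x m p-value matrix -> per-method combined p-values (length-B vectors)
.combine_block <- function(pv) {
  m <- ncol(pv)
  psi <- rowMeans(tanpi(0.5 - pv))
  list(
    cct = .cauchy_tail_p(psi),
    fisher = stats::pchisq(rowSums(-2 * log(pv)), df = 2 * m,
                           lower.tail = FALSE),
    minp = -expm1(m * log1p(-matrixStats_rowMins(pv)))
  )
}

# row minima without extra dependencies; pmin over columns is O(m) passes
# but each pass is vectorized C
matrixStats_rowMins <- function(x) {
  out <- x[, 1L]
  for (j in seq.int(2L, length.out = ncol(x) - 1L)) {
    out <- pmin(out, x[, j])
  }
  out
}

.methods <- c("cct", "fisher", "minp")

# core rejection-counting loop shared by the drivers
.count_rejections <- function(config) {
  B_max <- max(1L, floor(.block_budget / (config$n * config$m)))
  rej <- matrix(0, nrow = 3L, ncol = length(config$alpha),
                dimnames = list(.methods, NULL))
  done <- 0L
  while (done < config$M) {
    B <- min(B_max, config$M - done)
    pv <- .simulate_pvalue_block(config, B)
    comb <- .combine_block(pv)
    for (k in .methods) {
      rej[k, ] <- rej[k, ] +
        vapply(config$alpha, function(a) sum(comb[[k]] < a), 0)
    }
    done <- done + B
  }
  rej
}

#' Type-I error (size) study for one scenario
#'
#' Runs M all-null replicates of the scenario: generate n observations of
#' the m count variables (independent, or coupled through the configured
#' copula), compute the m two-sided normal-approximation Z-test p-values
#' against the null means, combine them with the CCT, Fisher and MinP
#' tests, and record the fraction of replicates whose combined p-value
#' falls below each significance level, with binomial Monte Carlo
#' standard errors. Deterministic given `config$seed`.
#'
#' @param config a [scenario_config()] whose null means equal the true
#'   means; a mismatch triggers a warning (the run is then a power run).
#' @return a `"rejection_table"`: a data frame with columns `method`,
#'   `alpha`, `rate`, `mc_se` and attributes recording the scenario.
#' @examples
#' cfg <- scenario_config(m = 10, r = 30, n = 30, M = 500, seed = 1)
#' run_type1(cfg)
#' @export
run_type1 <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(abs(config$null_means - config$true_means) > 1e-12)) {
    warning("null means differ from the data-generating means: ",
            "this is a power configuration, not a type-I error run",
            call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  rej <- .count_rejections(config)
  rate <- as.vector(t(rej)) / config$M
  out <- data.frame(
    method = rep(.methods, each = length(config$alpha)),
    alpha = rep(config$alpha, times = 3L),
    rate = rate,
    mc_se = sqrt(rate * (1 - rate) / config$M),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  class(out) <- c("rejection_table", "data.frame")
  out
}

#' @export
print.rejection_table <- function(x, digits = 4, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    cat("Monte Carlo rejection rates (M = ", cfg$M, " replicates)\n\n",
        sep = "")
  }
  print.data.frame(format(as.data.frame(x), digits = digits),
                   row.names = FALSE)
  invisible(x)
}

#' Sparse-signal power study
#'
#' Power of the three combination tests against sample size, in the
#' sparse-signal layout: m - 1 null variables with success parameter
#' `r_null` and one signal variable with `r_signal`, all tested against
#' the null mean implied by `r_null` (so only the signal variable's test
#' has a shifted mean). At p = 0.5 the defaults place nine nulls at
#' NB(10, 0.5) and one signal at NB(11, 0.5), i.e. a mean shift of 1
#' against a null variance of 20. Rejection is at level `alpha` on the
#' combined p-value. Setting `r_signal = r_null` gives the all-null
#' configuration, whose "power" collapses to the type-I error rate.
#'
#' @param n_values sample sizes to sweep.
#' @param structures subset of `"independence"`, `"clayton"`, `"gumbel"`.
#' @param theta copula parameter for the dependent structures.
#' @param m number of variables.
#' @param r_null,r_signal success parameters of the null and signal
#'   variables.
#' @param p shared success probability.
#' @param M replicates per (structure, n) cell.
#' @param alpha significance level for rejection.
#' @param seed optional integer seed (one stream across all cells).
#' @return a `"power_curve"`: data frame with columns `structure`,
#'   `method`, `n`, `power`, `mc_se`.
#' @examples
#' pw <- run_power(n_values = c(10, 30), structures = "independence",
#'                 M = 200, seed = 1)
#' @export
run_power <- function(n_values = c(5, 10, 30, 50, 100, 150, 200, 300, 500, 1000),
                      structures = c("independence", "clayton", "gumbel"),
                      theta = 3, m = 10, r_null = 10, r_signal = 11,
                      p = 0.5, M = 10000, alpha = 0.05, seed = NULL) {
  if (length(n_values) < 1L) stop("n_values must be non-empty", call. = FALSE)
  structures <- match.arg(structures, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  r_values <- c(rep(r_null, m - 1L), r_signal)
  null_means <- rep(r_null * (1 - p) / p, m)
  rows <- list()
  for (s in structures) {
    cop <- if (s == "independence") NULL else
      copula_spec(s, theta = theta, dim = m)
    for (n in sort(n_values)) {
      cfg <- scenario_config(m = m, r = r_values, p = p, n = n, M = M,
                             alpha = alpha, copula = cop,
                             null_means = null_means, seed = NULL)
      rej <- .count_rejections(cfg)
      rate <- rej[, 1L] / M
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s, method = .methods, n = n, power = rate,
        mc_se = sqrt(rate * (1 - rate) / M), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("power_curve", "data.frame")
  out
}

#' @export
plot.power_curve <- function(x, ...) {
  structures <- unique(x$structure)
  old <- graphics::par(mfrow = c(1, length(structures)))
  on.exit(graphics::par(old))
  for (s in structures) {
    d <- x[x$structure == s, ]
    w <- stats::reshape(d[, c("method", "n", "power")], direction = "wide",
                        idvar = "n", timevar = "method")
    graphics::matplot(w$n, w[, -1L], type = "b", pch = 1:3, lty = 1:3,
                      col = 1:3, xlab = "sample size n", ylab = "power",
                      ylim = c(0, 1), main = s, ...)
    graphics::legend("bottomright", legend = sub("^power\\.", "", names(w)[-1L]),
                     pch = 1:3, lty = 1:3, col = 1:3, bty = "n")
  }
  invisible(x)
}

#' Sensitivity of the CCT type-I error to skewness
#'
#' For every (r, n) pair in the grids, reports the standardized skewness
#' of the NB(r, p) sample mean alongside the Monte Carlo CCT type-I error
#' rate at level `alpha` with m independent variables. The skewness
#' column is analytic (independent of M); the rate column is simulated.
#'
#' @param r_grid success parameters to scan.
#' @param n_grid sample sizes to scan.
#' @param m number of independent variables per scenario.
#' @param M replicates per cell.
#' @param p shared success probability.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return data frame with columns `r`, `n`, `skewness` (2 d.p. in the
#'   companion `skewness_2dp` column, full precision in `skewness`),
#'   `cct_rate`, `mc_se`.
#' @export
run_sensitivity <- function(r_grid, n_grid, m = 30, M = 10000, p = 0.5,
                            alpha = 0.05, seed = NULL) {
  if (length(r_grid) < 1L || length(n_grid) < 1L) {
    stop("r_grid and n_grid must be non-empty", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(r = r_grid, n = n_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$r[i]; n <- grid$n[i]
    cfg <- scenario_config(m = m, r = r, p = p, n = n, M = M,
                           alpha = alpha, seed = NULL)
    rate <- .count_rejections(cfg)["cct", 1L] / M
    sk <- standardized_skewness(nb_params(r, p), n)
    data.frame(r = r, n = n, skewness = sk, skewness_2dp = round(sk, 2),
               cct_rate = rate, mc_se = sqrt(rate * (1 - rate) / M))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Heatmap grid of averaged CCT type-I error rates
#'
#' For every (n, r) cell, averages the CCT type-I error rate over
#' `outer_reps` independent repetitions of an M-replicate study with m
#' independent NB(r, p) variables. With `outer_reps = 1` each cell is a
#' single [run_type1()] estimate. As n and r grow the cell values
#' approach the nominal level.
#'
#' @param n_grid,r_grid grids of sample sizes and success parameters.
#' @param m number of independent variables.
#' @param M replicates per inner study.
#' @param outer_reps number of repetitions averaged per cell.
#' @param p shared success probability.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return a `"cct_heatmap"`: a length(n_grid) x length(r_grid) matrix of
#'   averaged rates, dimnames `n` and `r`, with a plot method.
#' @export
run_heatmap_grid <- function(n_grid, r_grid, m = 30, M = 10000,
                             outer_reps = 1, p = 0.5, alpha = 0.05,
                             seed = NULL) {
  if (length(n_grid) < 1L || length(r_grid) < 1L) {
    stop("n_grid and r_grid must be non-empty", call. = FALSE)
  }
  if (outer_reps < 1) stop("outer_reps must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, length(n_grid), length(r_grid),
                dimnames = list(n = n_grid, r = r_grid))
  for (i in seq_along(n_grid)) {
    for (j in seq_along(r_grid)) {
      cfg <- scenario_config(m = m, r = r_grid[j], p = p, n = n_grid[i],
                             M = M, alpha = alpha, seed = NULL)
      rates <- vapply(seq_len(outer_reps), function(k) {
        .count_rejections(cfg)["cct", 1L] / M
      }, 0)
      out[i, j] <- mean(rates)
    }
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("cct_heatmap", class(out))
  out
}

#' @export
plot.cct_heatmap <- function(x, ...) {
  n_grid <- as.numeric(rownames(x))
  r_grid <- as.numeric(colnames(x))
  graphics::image(n_grid, r_grid, unclass(x), xlab = "sample size n",
                  ylab = "success parameter r",
                  main = "average CCT type-I error rate", ...)
  invisible(x)
}
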