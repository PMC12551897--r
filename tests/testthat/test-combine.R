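# Frozen expected values below were computed with a 50-digit
# arbitrary-precision evaluation of the Cauchy combination formulas
# (weighted tangent sum, then 0.5 - arctan(psi)/pi).

test_that("CCT matches high-precision oracle values", {
  oracle <- list(
    list(p = c(0.01, 0.5, 0.9),    expected = 0.03310336641341091),
    list(p = c(0.3, 0.7),          expected = 0.5),
    list(p = c(0.25, 0.5, 0.75),   expected = 0.5),
    list(p = c(1e-8, 0.5),         expected = 1.999999999999998e-8),
    list(p = c(0.9999, 0.99),      expected = 0.9998019795720613),
    list(p = c(0.78, 0.002, 0.74, 0.016, 0.89, 0.10),
         expected = 0.010774923290927891),
    list(p = c(0.94, 0.0015, 0.97, 0.79, 0.81),
         expected = 0.008217997785430131)
  )
  for (case in oracle) {
    res <- cct_combine(case$p)
    expect_lt(abs(res$combined_p - case$expected), 1e-12)
    expect_equal(res$m, length(case$p))
  }
  # statistic of the six-study example, same oracle
  expect_equal(cct_combine(c(0.78, 0.002, 0.74, 0.016, 0.89, 0.10))$statistic,
               29.530446736840357, tolerance = 1e-12)
})

test_that("Fisher and MinP follow their closed-form null laws", {
  p <- c(0.78, 0.002, 0.74, 0.016, 0.89, 0.10)
  f <- fisher_combine(p)
  expect_equal(f$statistic, -2 * sum(log(p)))
  expect_equal(f$combined_p, pchisq(f$statistic, df = 12, lower.tail = FALSE))
  expect_false(f$weights_used)

  mp <- minp_combine(c(0.01, 0.5, 0.9))
  expect_equal(mp$statistic, 0.01)
  expect_equal(mp$combined_p, 1 - 0.99^3, tolerance = 1e-15)
  expect_equal(minp_combine(c(0.5, 0.5))$combined_p, 0.75)
})

test_that("all three methods reduce to the identity at m = 1", {
  for (p in c(1e-10, 1e-6, 0.001, 0.025, 0.3, 0.5, 0.77, 0.999)) {
    expect_lt(abs(cct_combine(p)$combined_p - p), 1e-12)
    expect_lt(abs(minp_combine(p)$combined_p - p), 1e-12)
    expect_lt(abs(fisher_combine(p)$combined_p - p), 1e-12)
  }
})

test_that("decreasing any single p-value never increases the combined p", {
  set.seed(2024)
  for (rep in 1:25) {
    m <- sample(2:8, 1)
    p <- runif(m)
    i <- sample(m, 1)
    p2 <- p
    p2[i] <- p[i] * runif(1)
    for (fn in list(cct_combine, fisher_combine, minp_combine)) {
      expect_lte(fn(p2)$combined_p, fn(p)$combined_p)
    }
  }
})

test_that("weights are normalized and respected by the CCT only", {
  p <- c(0.1, 0.2, 0.3)
  w_raw <- c(1, 2, 3)
  a <- cct_combine(p, w_raw)
  b <- cct_combine(p, w_raw / sum(w_raw))
  expect_equal(a$combined_p, b$combined_p)
  expect_equal(sum(a$weights), 1, tolerance = 1e-12)
  # hand evaluation of the weighted tangent sum
  psi <- sum(w_raw / 6 * tan((0.5 - p) * pi))
  expect_equal(a$statistic, psi)
  # Fisher / MinP ignore weights but record that they did
  expect_equal(fisher_combine(p, w_raw)$combined_p,
               fisher_combine(p)$combined_p)
  expect_equal(minp_combine(p, w_raw)$combined_p, minp_combine(p)$combined_p)
  expect_false(fisher_combine(p, w_raw)$weights_used)
})

test_that("the stable tail branch agrees with the direct formula", {
  psi <- 10^seq(0, 6, length.out = 60)
  direct <- cctcount:::.cauchy_tail_p(psi, tail = FALSE)
  stable <- cctcount:::.cauchy_tail_p(psi, tail = TRUE)
  expect_lt(max(abs(stable - direct) / direct), 1e-10)
  # symmetric branch on the left tail
  direct_l <- cctcount:::.cauchy_tail_p(-psi, tail = FALSE)
  stable_l <- cctcount:::.cauchy_tail_p(-psi, tail = TRUE)
  expect_lt(max(abs(stable_l - direct_l)), 1e-12)
  # beyond the crossover the direct form would underflow to 0, but the
  # tail branch still returns the clipped input's Cauchy tail mass
  expect_equal(cct_combine(1e-300)$combined_p, cctcount:::.p_eps,
               tolerance = 0.1)
  expect_gt(cct_combine(1e-300)$combined_p, 0)
})

test_that("boundary p-values are clipped rather than propagated to Inf", {
  for (fn in list(cct_combine, fisher_combine, minp_combine)) {
    res <- fn(c(0, 0.5, 1))
    expect_true(is.finite(res$statistic))
    expect_true(res$combined_p > 0 && res$combined_p < 1)
  }
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(cct_combine(numeric(0)), "at least one")
  expect_error(cct_combine(c(0.5, 1.5)), "\\[0, 1\\]")
  expect_error(cct_combine(c(0.5, NA)), "finite")
  expect_error(cct_combine(c(0.2, 0.4), weights = c(-1, 2)), "non-negative")
  expect_error(cct_combine(c(0.2, 0.4), weights = c(0, 0)), "zero")
  expect_error(cct_combine(c(0.2, 0.4), weights = 1), "length")
})

test_that("combine_pvalues dispatches and 'all' returns one row per method", {
  p <- c(0.05, 0.2, 0.9)
  expect_equal(combine_pvalues(p, "cct")$combined_p, cct_combine(p)$combined_p)
  all3 <- combine_pvalues(p, "all")
  expect_equal(all3$method, c("cct", "fisher", "minp"))
  expect_equal(all3$combined_p[2], fisher_combine(p)$combined_p)
})

test_that("each method holds its size on independent uniform p-values", {
  set.seed(90210)
  M <- 10000
  pv <- matrix(runif(M * 8), M, 8)
  rates <- reject_rates(pv, alpha = 0.05)
  for (k in names(rates)) {
    expect_within(rates[[k]], 0.05, band3(0.05, M))
  }
})
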