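test_that("scenario_config validates, broadcasts and defaults to all-null", {
  cfg <- scenario_config(m = 10, r = 30, n = 30, M = 100, seed = 1)
  expect_equal(cfg$r_values, rep(30, 10))
  expect_equal(cfg$null_means, rep(30, 10))   # r(1-p)/p at p = 0.5
  expect_equal(cfg$null_vars, rep(60, 10))
  expect_error(scenario_config(m = 0, r = 5), "positive integer")
  expect_error(scenario_config(m = 2, r = -1), "positive")
  expect_error(scenario_config(m = 2, r = 5, alpha = 1.2), "alpha")
  expect_error(scenario_config(m = 3, r = 5,
                               copula = copula_spec("clayton", theta = 2,
                                                    dim = 2)),
               "dimension")
})

test_that("run_type1 is bit-reproducible given the seed", {
  cfg <- scenario_config(m = 5, r = 10, n = 20, M = 400, seed = 404)
  a <- run_type1(cfg)
  b <- run_type1(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a single replicate yields a degenerate 0/1 rate", {
  cfg <- scenario_config(m = 5, r = 10, n = 20, M = 1, seed = 9)
  tab <- run_type1(cfg)
  expect_true(all(tab$rate %in% c(0, 1)))
  expect_true(all(tab$mc_se == 0))
})

test_that("rejection rates are monotone in alpha within a run", {
  cfg <- scenario_config(m = 10, r = 30, n = 30, M = 1000,
                         alpha = c(0.01, 0.05, 0.2), seed = 77)
  tab <- run_type1(cfg)
  for (k in unique(tab$method)) {
    r <- tab$rate[tab$method == k][order(tab$alpha[tab$method == k])]
    expect_true(all(diff(r) >= 0))
  }
})

test_that("a power configuration passed to run_type1 warns", {
  cfg <- scenario_config(m = 3, r = c(10, 10, 11), n = 10, M = 10,
                         null_means = rep(10, 3), seed = 3)
  expect_warning(run_type1(cfg), "power configuration")
})

test_that("Fisher controls size across the independent scenario grid", {
  # full independent grid (m x r crossing) at a reduced replication count
  i <- 0
  for (m in c(10, 50, 100)) {
    for (r in c(5, 30, 50)) {
      i <- i + 1
      cfg <- scenario_config(m = m, r = r, n = 30, M = 2000, alpha = 0.05,
                             seed = 7000 + i)
      tab <- run_type1(cfg)
      expect_within(tab$rate[tab$method == "fisher"], 0.05,
                    band3(0.05, 2000))
    }
  }
})

test_that("dependence inflates Fisher but not the CCT (Clayton theta = 3)", {
  cop <- copula_spec("clayton", theta = 3, dim = 10)
  cfg <- scenario_config(m = 10, r = 30, n = 30, M = 2000, alpha = 0.05,
                         copula = cop, seed = 515)
  tab <- run_type1(cfg)
  expect_gt(tab$rate[tab$method == "fisher"], 0.10)
  expect_lt(tab$rate[tab$method == "cct"], 0.10)
})

test_that("MinP is conservative under strong Gumbel dependence", {
  cop <- copula_spec("gumbel", theta = 5, dim = 50)
  cfg <- scenario_config(m = 50, r = 30, n = 30, M = 2000, alpha = 0.05,
                         copula = cop, seed = 616)
  tab <- run_type1(cfg)
  expect_lt(tab$rate[tab$method == "minp"], 0.02)
})

test_that("run_power sweeps sample sizes and collapses to size when null", {
  pw <- run_power(n_values = c(10, 50), structures = "independence",
                  m = 5, M = 300, seed = 11)
  expect_s3_class(pw, "power_curve")
  expect_equal(sort(unique(pw$n)), c(10, 50))
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  # no-signal configuration: "power" is just the type-I error rate
  null_pw <- run_power(n_values = 30, structures = "independence",
                       m = 10, r_null = 10, r_signal = 10, M = 1000,
                       seed = 12)
  for (k in unique(null_pw$method)) {
    expect_within(null_pw$power[null_pw$method == k], 0.05,
                  band3(0.05, 1000))
  }
  expect_error(run_power(n_values = numeric(0)), "non-empty")
})

test_that("sensitivity table couples the analytic skewness to the MC rate", {
  tab <- run_sensitivity(r_grid = c(5, 50), n_grid = 30, m = 5, M = 200,
                         seed = 31)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$skewness_2dp, c(0.17, 0.05))
  # the skewness column is analytic: identical under a different M
  tab2 <- run_sensitivity(r_grid = c(5, 50), n_grid = 30, m = 5, M = 50,
                          seed = 32)
  expect_identical(tab$skewness, tab2$skewness)
})

test_that("heatmap with outer_reps = 1 reduces to a single type-1 estimate", {
  h <- run_heatmap_grid(n_grid = 20, r_grid = 10, m = 5, M = 500,
                        outer_reps = 1, seed = 2718)
  t1 <- run_type1(scenario_config(m = 5, r = 10, n = 20, M = 500,
                                  alpha = 0.05, seed = 2718))
  expect_equal(unname(h[1, 1]), t1$rate[t1$method == "cct" &
                                          t1$alpha == 0.05])
  expect_equal(dim(h), c(1L, 1L))
})

test_that("averaging outer repetitions shrinks the cell variance", {
  # variance of a mean of k i.i.d. estimates scales like 1/k
  cells1 <- replicate(40, run_heatmap_grid(20, 10, m = 3, M = 60,
                                           outer_reps = 1)[1, 1])
  cells4 <- replicate(40, run_heatmap_grid(20, 10, m = 3, M = 60,
                                           outer_reps = 4)[1, 1])
  expect_lt(var(cells4), var(cells1))
})
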