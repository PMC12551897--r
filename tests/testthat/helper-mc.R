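# Monte Carlo helpers shared across tests.

# 3-standard-error binomial band around a reference rejection rate
band3 <- function(rate, M) 3 * sqrt(rate * (1 - rate) / M)

# conservative standard error of the empirical Kendall's tau at sample
# size n (exact under independence, close enough for the band checks)
tau_se <- function(n) sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))

expect_within <- function(value, center, halfwidth) {
  expect_true(abs(value - center) <= halfwidth,
              label = sprintf("%.5f within %.5f +/- %.5f",
                              value, center, halfwidth))
}

# rejection rate of each combination method on a matrix of p-value
# vectors (rows = replicates), at one level
reject_rates <- function(pv, alpha = 0.05) {
  comb <- cctcount:::.combine_block(cctcount:::.clip_p(pv))
  vapply(comb, function(p) mean(p < alpha), 0)
}
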