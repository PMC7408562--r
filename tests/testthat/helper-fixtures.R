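# Shared fixtures, all generated in code.

gaussian_spectrum <- function(mu, sigma, amp = 1, from = mu - 5 * sigma,
                              to = mu + 5 * sigma, by = 0.5,
                              kind = "emission") {
  g <- seq(from, to, by = by)
  spectrum(g, amp * exp(-(g - mu)^2 / (2 * sigma^2)), kind = kind)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
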