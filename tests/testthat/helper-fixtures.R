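# Small deterministic fixtures used across test files.

tiny_series <- function(values = c(1, 5, 2, 0), dt = 1) {
  concentration_series(values, dt, "t1", "s1")
}

# Independent Gamma MLE oracle: solve the profile score equation
# log(a) - digamma(a) = log(mean(x)) - mean(log(x)) by root finding,
# then b = mean(x) / a. Independent of MASS::fitdistr's optimiser.
gamma_mle_oracle <- function(x) {
  rhs <- log(mean(x)) - mean(log(x))
  a <- stats::uniroot(function(a) log(a) - digamma(a) - rhs,
    interval = c(1e-6, 1e6), tol = 1e-12
  )$root
  c(shape = a, scale = mean(x) / a)
}
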