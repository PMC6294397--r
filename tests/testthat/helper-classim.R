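# Shared fixtures and small oracles for the test suite.

# Exact null expectation of a drive computed from n iid Gaussian descriptor
# elements: E[log(RMS/RMS*)] = (digamma(n/2) - log(n/2)) / 2, the mean of the
# log of a chi_n/sqrt(n) variate. The idealised statement "expected drive of
# a decoupled process is 0" holds up to this small-sample term (-0.039 for
# n = 13).
lambda_null_mean <- function(n) (digamma(n / 2) - log(n / 2)) / 2

# A quick mid-grid condition.
quick_cond <- function(task = "bright") condition_spec(task, 3, 2)

# 13-tap sampling of the default front-end DOG at the bar positions.
dog13 <- function(spec = dog_spec()) {
  f <- dog_filter(spec)
  half <- (length(f) - 1) / 2
  f[half + 1 + (-6:6)]
}

# Simulate one session and return trials + responses.
quick_session <- function(cond, config, n) {
  tr <- make_trials(cond, n)
  list(trials = tr, responses = respond(tr, config))
}
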