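# Shared fixtures: small, fast simulator configurations.

# chunked 125 Hz run with default transport
quick_chunked_cfg <- function(seed, rate = 125, ...) {
  sim_config(rate = rate, duration = 20, seed = seed, ...)
}

# clean (per-sample) transport at 250 Hz with no transport delay, so the
# measured lag is the injected hardware lag alone
quick_clean_cfg <- function(seed, rate = 250, ...) {
  sim_config(rate = rate, duration = 20, seed = seed, transport_delay = 0,
             stamp_noise_sd = 0, ...)
}

# a chunk-clustered raw timestamp vector: chunks of given sizes received at
# the given times, with tiny within-chunk stamp spacing
clustered_raw <- function(reception, sizes, spacing = 2e-4) {
  unlist(mapply(function(t0, n) t0 + (seq_len(n) - 1) * spacing,
                reception, sizes, SIMPLIFY = FALSE))
}

# closed-form per-segment OLS oracle for the regular dejitter, written
# independently of the implementation (explicit sums, not lm)
ols_oracle <- function(ts, gap_threshold = 1.0) {
  d <- diff(ts)
  starts <- c(1L, which(d > gap_threshold | d < -gap_threshold) + 1L)
  ends <- c(starts[-1L] - 1L, length(ts))
  out <- ts
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    m <- length(idx)
    if (m < 2) next
    x <- seq_len(m)
    y <- ts[idx]
    beta <- (m * sum(x * y) - sum(x) * sum(y)) / (m * sum(x^2) - sum(x)^2)
    alpha <- mean(y) - beta * mean(x)
    out[idx] <- alpha + beta * x
  }
  out
}
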