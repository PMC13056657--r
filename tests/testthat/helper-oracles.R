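# Independent oracles and small fixture builders shared across tests.

# naive two-pass Pearson correlation, kept deliberately independent of
# the package's moving-window implementation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# trend series straight from a numeric vector (fully covered windows)
make_trend <- function(values, variable = "ICP", spacing = 10,
                       start = 0) {
  trend_series(start + spacing * seq_along(values), values,
               rep(1, length(values)), variable, spacing)
}

# small noise-free config for deterministic pipeline checks
quiet_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, noise_free = TRUE, ...)
}
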