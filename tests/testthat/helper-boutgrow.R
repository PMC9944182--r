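# Shared fixtures and independent oracles for the test suite.

# The six published diet-by-instar switch-rate point estimates (per hour).
rate_pairs <- function() {
  list(diet4 = c(10.25, 4.93), tobacco4 = c(16.21, 10.19),
       devilsclaw4 = c(56.22, 24.36), diet5 = c(16.85, 11.05),
       tobacco5 = c(10.7, 12.63), devilsclaw5 = c(59.43, 37.99))
}

# Build a bout sequence directly from a vector of durations in seconds,
# alternating states starting from `first`.
seq_from_durations <- function(dur_s, first = "nonfeeding") {
  states <- rep(c(first, setdiff(c("feeding", "nonfeeding"), first)),
                length.out = length(dur_s))
  ends <- cumsum(dur_s)
  bout_sequence(states, c(0, ends[-length(ends)]), ends,
                ends[length(ends)] / 3600)
}

# Random alternating bout sequence with a mix of short and long bouts, for
# property tests of the minimum-bout filter.
random_bout_seq <- function(n_bouts, short_prob = 0.3) {
  dur <- ifelse(runif(n_bouts) < short_prob, runif(n_bouts, 0.5, 4.9),
                runif(n_bouts, 5, 400))
  seq_from_durations(dur, sample(c("feeding", "nonfeeding"), 1))
}

# Brute-force reference for the minimum-bout filter: repeatedly absorb the
# first interior short bout, recomputing from scratch each pass.
filter_reference <- function(seq, min_s = 5) {
  df <- seq$bouts
  repeat {
    n <- nrow(df)
    if (n < 3) break
    dur <- df$end_s - df$start_s
    short <- which(dur < min_s & seq_len(n) > 1 & seq_len(n) < n)
    if (length(short) == 0) break
    i <- short[1]
    df$end_s[i - 1] <- df$end_s[i + 1]
    df <- df[-c(i, i + 1), , drop = FALSE]
  }
  bout_sequence(df$state, df$start_s, df$end_s, seq$Z_h)
}

# Two-sided Kolmogorov distance between an empirical sample of occupation
# times (which has an atom at 0) and the analytic CDF.
ks_occupation <- function(W, Z, rates, start_state = "nonfeeding") {
  n <- length(W)
  u <- sort(unique(W))
  cnt <- as.numeric(table(factor(W, levels = u)))
  Fn_hi <- cumsum(cnt) / n
  Fn_lo <- Fn_hi - cnt / n
  Fc <- occupation_cdf(u, Z, rates, start_state)
  atom <- if (start_state == "nonfeeding") exp(-rates$lambda_n * Z) else 0
  Fc_lo <- Fc - ifelse(u == 0, atom, 0)
  max(abs(Fn_hi - Fc), abs(Fn_lo - Fc_lo))
}

# Independent transient-mean formula (re-derived, not the package's code
# path): E[W(T)]/T from a nonfeeding start.
transient_fraction_oracle <- function(lambda_f, lambda_n, T_h) {
  r <- lambda_f + lambda_n
  p <- lambda_n / r
  p * (1 - (1 - exp(-r * T_h)) / (r * T_h))
}
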