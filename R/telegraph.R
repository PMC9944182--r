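#' Switch rates of the two-state feeding process
#'
#' The behavioural model assumes a larva alternates between feeding and
#' nonfeeding with exponentially distributed bout durations: `lambda_f` is
#' the rate of leaving the feeding state and `lambda_n` the rate of leaving
#' the nonfeeding state, both in switches per hour.
#'
#' @param lambda_f Rate of switching out of feeding, per hour (> 0).
#' @param lambda_n Rate of switching out of nonfeeding, per hour (> 0).
#' @return An object of class `switch_rates`.
#' @examples
#' switch_rates(10.25, 4.93)
#' @export
switch_rates <- function(lambda_f, lambda_n) {
  stopifnot(is.numeric(lambda_f), is.numeric(lambda_n),
            length(lambda_f) == 1, length(lambda_n) == 1)
  if (!is.finite(lambda_f) || !is.finite(lambda_n) ||
      lambda_f <= 0 || lambda_n <= 0) {
    stop("switch rates must be strictly positive and finite", call. = FALSE)
  }
  structure(list(lambda_f = lambda_f, lambda_n = lambda_n),
            class = "switch_rates")
}

#' @export
print.switch_rates <- function(x, ...) {
  cat(sprintf("switch rates (per hour): lambda_f = %.4g, lambda_n = %.4g\n",
              x$lambda_f, x$lambda_n))
  invisible(x)
}

as_switch_rates <- function(x) {
  if (inherits(x, "switch_rates")) return(x)
  if (is.numeric(x) && length(x) == 2) return(switch_rates(x[[1]], x[[2]]))
  stop("cannot interpret 'rates'; supply switch_rates() or a length-2 numeric",
       call. = FALSE)
}

#' Construct a bout sequence
#'
#' A bout sequence records one individual's alternation between feeding and
#' nonfeeding states over a trial window of length `Z_h` hours.  Bouts are
#' contiguous, non-overlapping, strictly alternating in state, start at 0 and
#' end at `Z_h * 3600` seconds.
#'
#' @param state Character vector, each `"feeding"` or `"nonfeeding"`.
#' @param start_s,end_s Numeric vectors of bout start/end times in seconds
#'   from trial start.
#' @param Z_h Trial window length in hours.
#' @return An object of class `bout_sequence`: a list with elements `bouts`
#'   (data frame `state`, `start_s`, `end_s`) and `Z_h`.
#' @export
bout_sequence <- function(state, start_s, end_s, Z_h) {
  df <- data.frame(state = as.character(state), start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s), stringsAsFactors = FALSE)
  seq <- structure(list(bouts = df, Z_h = as.numeric(Z_h)),
                   class = "bout_sequence")
  validate_bout_sequence(seq)
  seq
}

validate_bout_sequence <- function(seq, where = "bout sequence") {
  df <- seq$bouts
  Zs <- seq$Z_h * SECONDS_PER_HOUR
  bad <- function(msg) stop(sprintf("%s: %s", where, msg), call. = FALSE)
  if (nrow(df) < 1) bad("no bouts")
  if (!all(df$state %in% c("feeding", "nonfeeding")))
    bad("states must be 'feeding' or 'nonfeeding'")
  if (any(df$end_s - df$start_s < 0)) bad("negative bout duration")
  if (abs(df$start_s[1]) > 1e-9) bad("first bout must start at 0")
  if (abs(df$end_s[nrow(df)] - Zs) > 1e-6)
    bad(sprintf("last bout must end at the window (%g s)", Zs))
  if (nrow(df) > 1) {
    if (any(abs(df$start_s[-1] - df$end_s[-nrow(df)]) > 1e-6))
      bad("bouts must be contiguous (gap or overlap found)")
    if (any(df$state[-1] == df$state[-nrow(df)]))
      bad("states must strictly alternate")
  }
  invisible(seq)
}

#' @export
print.bout_sequence <- function(x, ...) {
  cat(sprintf("bout sequence: %d bouts over %.3g h (feeding time %.4g h)\n",
              nrow(x$bouts), x$Z_h, total_feeding_time(x)))
  invisible(x)
}

#' Simulate a bout sequence from the telegraph model
#'
#' Event-driven simulation: exponential sojourns with rate `lambda_n` in the
#' nonfeeding state and `lambda_f` in the feeding state, truncated at the
#' window end.
#'
#' @param rates A [switch_rates()] object.
#' @param Z Window length in hours.
#' @param start_state State at time 0; trials and the fitted likelihood both
#'   assume `"nonfeeding"` (larvae were food-deprived before trials).
#' @param seed Optional integer seed for reproducibility.
#' @return A [bout_sequence()].
#' @examples
#' simulate_bouts(switch_rates(10.25, 4.93), Z = 1, seed = 1)
#' @export
simulate_bouts <- function(rates, Z = 1,
                           start_state = c("nonfeeding", "feeding"),
                           seed = NULL) {
  rates <- as_switch_rates(rates)
  start_state <- match.arg(start_state)
  if (!is.numeric(Z) || length(Z) != 1 || !is.finite(Z) || Z <= 0)
    stop("Z must be a positive finite number of hours", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Zs <- Z * SECONDS_PER_HOUR
  state <- start_state
  t <- 0
  st <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  repeat {
    rate_h <- if (state == "feeding") rates$lambda_f else rates$lambda_n
    s <- rexp(1, rate_h) * SECONDS_PER_HOUR
    end <- min(t + s, Zs)
    st <- c(st, state); t0 <- c(t0, t); t1 <- c(t1, end)
    if (t + s >= Zs) break
    t <- end
    state <- if (state == "feeding") "nonfeeding" else "feeding"
  }
  bout_sequence(st, t0, t1, Z)
}

#' Total feeding time of a bout sequence
#'
#' @param seq A [bout_sequence()].
#' @return Total time in the feeding state, in hours.
#' @export
total_feeding_time <- function(seq) {
  validate_bout_sequence(seq)
  f <- seq$bouts$state == "feeding"
  sum(seq$bouts$end_s[f] - seq$bouts$start_s[f]) / SECONDS_PER_HOUR
}

#' Drop short bouts, keeping the surrounding state
#'
#' Observational rule used when scoring trials: a bout shorter than
#' `min_seconds` is disregarded and the surrounding state is maintained.
#' Interior short bouts are absorbed and their neighbours (which share a
#' state) merge; the scan restarts after each merge, left to right, until no
#' interior bout is shorter than the threshold.  The first and last bouts are
#' never absorbed (they have no surrounding state on both sides).  Total
#' duration is preserved exactly.
#'
#' @param seq A [bout_sequence()].
#' @param min_seconds Minimum bout length retained, seconds (default 5).
#' @return A filtered [bout_sequence()].
#' @export
apply_min_bout_filter <- function(seq, min_seconds = 5) {
  validate_bout_sequence(seq)
  df <- seq$bouts
  repeat {
    n <- nrow(df)
    if (n < 3) break
    dur <- df$end_s - df$start_s
    idx <- which(dur[-c(1, n)] < min_seconds)
    if (length(idx) == 0) break
    i <- idx[1] + 1L                       # first interior short bout
    # absorb bout i: neighbours i-1 and i+1 share a state and merge
    df$end_s[i - 1L] <- df$end_s[i + 1L]
    df <- df[-c(i, i + 1L), , drop = FALSE]
    rownames(df) <- NULL
  }
  bout_sequence(df$state, df$start_s, df$end_s, seq$Z_h)
}

#' Log-density of total feeding time within a window
#'
#' Distribution of the occupation time `W` of the feeding state over a window
#' of length `Z` hours for the telegraph process.  Starting from nonfeeding
#' there is an atom `P(W = 0) = exp(-lambda_n Z)`; for `0 < x < Z`, with
#' `y = Z - x` and `q = 2 sqrt(lambda_n lambda_f x y)`,
#' \deqn{f(x) = e^{-\lambda_f x - \lambda_n y}\left[\lambda_n I_0(q) +
#'   \sqrt{\lambda_n \lambda_f y / x}\, I_1(q)\right]}
#' where \eqn{I_0, I_1} are modified Bessel functions of the first kind,
#' evaluated in exponentially scaled form for numerical stability.  `x = Z`
#' returns the continuous limit `lambda_n exp(-lambda_f Z)` (no atom at `Z`
#' from a nonfeeding start).  A feeding start is handled by the reflection
#' `f_feed(x; lambda_f, lambda_n) = f_nonfeed(Z - x; lambda_n, lambda_f)`.
#'
#' @param x Total feeding time(s), hours, in `[0, Z]`.  Values of exactly 0
#'   return the log of the atom (a probability, not a density).
#' @param Z Window length in hours (scalar or vector matching `x`).
#' @param rates A [switch_rates()] object.
#' @param start_state State at time 0.
#' @return Log-density (log-probability at the atom), same length as `x`.
#' @export
occupation_log_density <- function(x, Z, rates,
                                   start_state = c("nonfeeding", "feeding")) {
  rates <- as_switch_rates(rates)
  start_state <- match.arg(start_state)
  Z <- rep_len(as.numeric(Z), length(x))
  if (any(!is.finite(x)) || any(x < 0 - 1e-12) || any(x > Z + 1e-12))
    stop("x must lie in [0, Z]", call. = FALSE)
  if (start_state == "feeding") {
    # occupation of feeding from a feeding start == occupation of nonfeeding
    # from a nonfeeding start under swapped rates
    return(occupation_log_density(Z - x, Z,
                                  switch_rates(rates$lambda_n, rates$lambda_f),
                                  "nonfeeding"))
  }
  a <- rates$lambda_f; b <- rates$lambda_n
  out <- numeric(length(x))
  atom <- x <= 0
  out[atom] <- -b * Z[atom]
  if (any(!atom)) {
    xi <- pmin(x[!atom], Z[!atom] * (1 - 1e-12))
    y <- Z[!atom] - xi
    q <- 2 * sqrt(a * b * xi * y)
    cc <- sqrt(a * b * y / xi)
    S <- b * besselI(q, 0, expon.scaled = TRUE) +
      cc * besselI(q, 1, expon.scaled = TRUE)
    out[!atom] <- log(S) + q - a * xi - b * y
  }
  out
}

#' Cumulative distribution of total feeding time
#'
#' `P(W <= x)` for the occupation time of the feeding state, computed as the
#' atom at 0 plus a cumulative trapezoidal integral of the continuous density
#' on a fine uniform grid (the density is smooth and bounded on `(0, Z)`).
#'
#' @inheritParams occupation_log_density
#' @param n_grid Number of grid intervals for the integral.
#' @return CDF values, same length as `x`.
#' @export
occupation_cdf <- function(x, Z, rates,
                           start_state = c("nonfeeding", "feeding"),
                           n_grid = 20000L) {
  rates <- as_switch_rates(rates)
  start_state <- match.arg(start_state)
  stopifnot(length(Z) == 1)
  g <- seq(0, Z, length.out = n_grid + 1L)
  fg <- numeric(n_grid + 1L)
  fg[-1] <- exp(occupation_log_density(g[-1], Z, rates, start_state))
  fg[1] <- exp(occupation_log_density(Z * 1e-14, Z, rates, start_state))
  h <- Z / n_grid
  # cumulative trapezoid (grid is fine enough that trapezoid error << 1e-6)
  cum <- c(0, cumsum((fg[-1] + fg[-length(fg)]) / 2 * h))
  atom0 <- if (start_state == "nonfeeding") exp(-rates$lambda_n * Z) else 0
  atomZ <- if (start_state == "feeding") exp(-rates$lambda_f * Z) else 0
  cdf_g <- atom0 + cum
  out <- approx(g, cdf_g, xout = pmin(pmax(x, 0), Z), rule = 2)$y
  out[x >= Z] <- atom0 + cum[length(cum)] + atomZ
  out
}

#' Expected fraction of time spent feeding over a finite window
#'
#' Transient mean occupancy of the feeding state: with `r = lambda_n +
#' lambda_f` and stationary fraction `pi = lambda_n / r`, a nonfeeding start
#' gives `E[W(T)]/T = pi [1 - (1 - exp(-r T)) / (r T)]`; a feeding start
#' gives `pi + (1 - pi)(1 - exp(-r T)) / (r T)`.
#'
#' @param rates A [switch_rates()] object.
#' @param T_h Window length in hours (> 0), vectorised.
#' @param start_state State at time 0.
#' @return Expected feeding fraction(s) in `[0, 1]`.
#' @export
expected_feeding_fraction <- function(rates, T_h,
                                      start_state = c("nonfeeding", "feeding")) {
  rates <- as_switch_rates(rates)
  start_state <- match.arg(start_state)
  if (any(!is.finite(T_h)) || any(T_h <= 0))
    stop("T_h must be positive and finite", call. = FALSE)
  r <- rates$lambda_f + rates$lambda_n
  pi_f <- rates$lambda_n / r
  relax <- (1 - exp(-r * T_h)) / (r * T_h)
  if (start_state == "nonfeeding") pi_f * (1 - relax)
  else pi_f + (1 - pi_f) * relax
}

#' Stationary fraction of time spent feeding
#'
#' Long-run proportion of time in the feeding state,
#' `lambda_n / (lambda_n + lambda_f)`.
#'
#' @param rates A [switch_rates()] object.
#' @return A fraction in (0, 1).
#' @export
stationary_feeding_fraction <- function(rates) {
  rates <- as_switch_rates(rates)
  rates$lambda_n / (rates$lambda_n + rates$lambda_f)
}

#' @importFrom stats approx
NULL
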