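#' Generating truth for one diet-by-instar group
#'
#' Bundles the parameters used to generate synthetic data for one group:
#' switch rates, the alpha distribution, and the number of individuals.
#'
#' @param diet One of `"diet"` (artificial diet), `"tobacco"`,
#'   `"devilsclaw"` (or any label).
#' @param instar Integer instar (4 or 5 in the study design).
#' @param rates A [switch_rates()] object.
#' @param alpha An alpha distribution (`fit_alpha_distribution()` or
#'   `c(mean, sd)` in g/h).
#' @param n_individuals Number of individuals in the group (>= 1).
#' @return A list of class `group_truth`.
#' @export
group_truth <- function(diet, instar, rates, alpha, n_individuals) {
  stopifnot(n_individuals >= 1)
  structure(list(diet = as.character(diet), instar = as.integer(instar),
                 rates = as_switch_rates(rates),
                 alpha = as_alpha_distribution(alpha),
                 n_individuals = as.integer(n_individuals)),
            class = "group_truth")
}

#' Published point estimates for *Manduca sexta* on three diets
#'
#' Switch rates (per hour), alpha distributions (g/h) and group sizes for
#' the six diet-by-instar cells of the feeding-trial study (4th and 5th
#' instars on artificial diet, tobacco, and devil's claw).  These are the
#' default generating values for the synthetic-data module, so synthetic
#' runs live in the same parameter regime as the real experiment.
#'
#' @return Named list of [group_truth()] objects
#'   (`diet4`, `tobacco4`, `devilsclaw4`, `diet5`, `tobacco5`,
#'   `devilsclaw5`).
#' @export
msexta_defaults <- function() {
  list(
    diet4       = group_truth("diet", 4, switch_rates(10.25, 4.93),
                              c(0.04, 0.02), 18),
    tobacco4    = group_truth("tobacco", 4, switch_rates(16.21, 10.19),
                              c(0.05, 0.01), 19),
    devilsclaw4 = group_truth("devilsclaw", 4, switch_rates(56.22, 24.36),
                              c(0.04, 0.01), 11),
    diet5       = group_truth("diet", 5, switch_rates(16.85, 11.05),
                              c(0.15, 0.04), 17),
    tobacco5    = group_truth("tobacco", 5, switch_rates(10.7, 12.63),
                              c(0.11, 0.03), 10),
    devilsclaw5 = group_truth("devilsclaw", 5, switch_rates(59.43, 37.99),
                              c(0.14, 0.03), 11)
  )
}

#' Published 90% confidence intervals for the switch rates
#'
#' The bootstrapped 90% percentile intervals accompanying
#' [msexta_defaults()], per hour, used by the interval-overlap significance
#' rule.
#'
#' @return Data frame: `diet`, `instar`, `rate` (`"lambda_f"`/`"lambda_n"`),
#'   `lo`, `hi`.
#' @export
msexta_intervals <- function() {
  data.frame(
    diet = rep(c("diet", "tobacco", "devilsclaw"), times = 4),
    instar = rep(c(4L, 4L, 5L, 5L), each = 3),
    rate = rep(c("lambda_f", "lambda_n"), each = 3, times = 2),
    lo = c(7.48, 11.72, 36.33,   3.00, 7.32, 16.85,
           12.59, 6.2, 40.81,    8.15, 8, 25.23),
    hi = c(18.24, 30.84, 147.69, 10.19, 19.52, 57.95,
           29.53, 42.61, 187.89, 18.91, 46.23, 128.16)
  )
}

round_to <- function(x, unit) round(x / unit) * unit

#' Generate a synthetic bout log for one group
#'
#' Per individual: event-driven switching from a nonfeeding start over a
#' `Z`-hour window, switch times rounded to the nearest second (as in live
#' scoring), zero-length bouts merged away, then the minimum-bout filter
#' applied.
#'
#' @param truth A [group_truth()] object.
#' @param Z Trial length, hours (default 1).
#' @param min_bout_s Minimum-bout filter threshold, seconds (default 5; use
#'   0 to disable).
#' @param round_s Round switch times to the nearest second (default TRUE).
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for individual ids.
#' @return A bout-log data frame (one row per bout): `individual_id`,
#'   `diet`, `instar`, `state`, `start_s`, `end_s`, `trial_length_s`.
#' @export
generate_trials <- function(truth, Z = 1, min_bout_s = 5, round_s = TRUE,
                            seed = NULL, id_prefix = NULL) {
  stopifnot(inherits(truth, "group_truth"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(id_prefix))
    id_prefix <- sprintf("%s_i%d", truth$diet, truth$instar)
  rows <- lapply(seq_len(truth$n_individuals), function(i) {
    seq <- simulate_bouts(truth$rates, Z)
    if (round_s) seq <- round_bout_times(seq)
    if (min_bout_s > 0) seq <- apply_min_bout_filter(seq, min_bout_s)
    df <- seq$bouts
    data.frame(individual_id = sprintf("%s_%03d", id_prefix, i),
               diet = truth$diet, instar = truth$instar,
               state = df$state, start_s = df$start_s, end_s = df$end_s,
               trial_length_s = Z * SECONDS_PER_HOUR)
  })
  do.call(rbind, rows)
}

# round switch times to the nearest second; drop the zero-length bouts this
# can create and re-merge neighbours
round_bout_times <- function(seq) {
  df <- seq$bouts
  Zs <- seq$Z_h * SECONDS_PER_HOUR
  cuts <- round_to(df$end_s[-nrow(df)], 1)
  cuts <- pmin(pmax(cuts, 0), Zs)
  start <- c(0, cuts); end <- c(cuts, Zs)
  keep <- end - start > 0
  st <- df$state[keep]; start <- start[keep]; end <- end[keep]
  # merge consecutive same-state bouts left by dropped zero-length bouts
  if (length(st) > 1) {
    grp <- factor(cumsum(c(TRUE, st[-1] != st[-length(st)])))
    grp <- factor(grp, levels = unique(as.character(grp)))
    start <- tapply(start, grp, min); end <- tapply(end, grp, max)
    st <- tapply(st, grp, function(v) v[1])
  }
  bout_sequence(as.character(st), as.numeric(start), as.numeric(end), seq$Z_h)
}

#' Generate synthetic mass records for one group
#'
#' Emulates the molt-to-pretrial weighing design: elapsed times are uniform
#' on 22-26 h rounded to the quarter hour; each individual's alpha is drawn
#' from the group truth (truncated at 0); the expected mass gain is
#' `alpha * expected_feeding_fraction(rates, elapsed) * elapsed`, with
#' optional lognormal measurement noise on both weighings.
#'
#' @param truth A [group_truth()] object.
#' @param seed Optional integer seed.
#' @param noise_cv Coefficient of variation of lognormal measurement noise
#'   (default 0.02; 0 disables).
#' @param molt_mass `c(mean, sd)` in grams of the (truncated > 0) normal
#'   molt-mass distribution; defaults by instar: Normal(0.35, 0.08) for the
#'   4th, Normal(1.8, 0.4) for the 5th.  These molt-mass defaults are
#'   synthetic conventions, not measured values.
#' @return Mass-record data frame: `individual_id`, `diet`, `instar`,
#'   `mass_molt_g`, `mass_pretrial_g`, `elapsed_h`.
#' @export
generate_mass_records <- function(truth, seed = NULL, noise_cv = 0.02,
                                  molt_mass = NULL) {
  stopifnot(inherits(truth, "group_truth"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(molt_mass))
    molt_mass <- if (truth$instar <= 4) c(0.35, 0.08) else c(1.8, 0.4)
  n <- truth$n_individuals
  elapsed <- round_to(runif(n, 22, 26), 0.25)
  alpha_i <- sample_alpha(truth$alpha, n)
  m0 <- sample_truncated_normal(n, molt_mass[1], molt_mass[2], lower = 0)
  gain <- alpha_i * expected_feeding_fraction(truth$rates, elapsed) * elapsed
  noisy <- function(m) {
    if (noise_cv <= 0) return(m)
    sdl <- sqrt(log(1 + noise_cv^2))
    m * exp(rnorm(length(m), -sdl^2 / 2, sdl))
  }
  data.frame(individual_id = sprintf("%s_i%d_%03d", truth$diet, truth$instar,
                                     seq_len(n)),
             diet = truth$diet, instar = truth$instar,
             mass_molt_g = noisy(m0), mass_pretrial_g = noisy(m0 + gain),
             elapsed_h = elapsed)
}

#' Generate out-of-sample-style validation tables
#'
#' Emulates the independent historical data used for model validation: (a) a
#' pool of 4th-instar durations (lognormal), (b) initial 5th-instar masses
#' (normal, truncated > 0), and (c) age/mass-at-wandering records produced
#' by [simulate_maturity()] under optionally perturbed parameters, standing
#' in for a population separated from the training data by time and strain.
#'
#' @param dev A [development_params()] object.
#' @param truth A [group_truth()] object (rates and alpha of the group).
#' @param m0_dist `c(mean, sd)` grams of initial 5th-instar mass.
#' @param n Number of wandering records.
#' @param seed Optional integer seed.
#' @param duration_meanlog,duration_sdlog Lognormal parameters of the
#'   4th-instar duration pool, log-hours (defaults give median ~72 h).
#' @param n_durations,n_m0 Pool sizes for tables (a) and (b).
#' @param perturb Named list of multiplicative perturbations applied to the
#'   "observed" population only: `lambda_f`, `lambda_n`, `lambda` (both
#'   rates; note this leaves the stationary feeding fraction unchanged, so
#'   it mostly rescales process noise), `alpha_mean`, `mu`.
#' @return A list: `durations` (data frame `duration_h`), `initial_mass`
#'   (data frame `m0_g`), `wandering` (data frame `age_h`, `mass_g`,
#'   `diet`), and `params` echoing the generating values.
#' @export
generate_outofsample <- function(dev, truth, m0_dist, n = 500, seed = NULL,
                                 duration_meanlog = log(72),
                                 duration_sdlog = 0.18,
                                 n_durations = 200, n_m0 = 200,
                                 perturb = list()) {
  stopifnot(inherits(dev, "development_params"),
            inherits(truth, "group_truth"))
  if (!is.null(seed)) set.seed(seed)
  durations <- data.frame(
    duration_h = exp(rnorm(n_durations, duration_meanlog, duration_sdlog)))
  m0 <- data.frame(m0_g = sample_truncated_normal(n_m0, m0_dist[1],
                                                  m0_dist[2], lower = 0))
  p_lambda <- perturb$lambda %||% 1
  p_lf <- perturb$lambda_f %||% 1
  p_ln <- perturb$lambda_n %||% 1
  p_alpha <- perturb$alpha_mean %||% 1
  p_mu <- perturb$mu %||% 1
  rates_obs <- switch_rates(truth$rates$lambda_f * p_lambda * p_lf,
                            truth$rates$lambda_n * p_lambda * p_ln)
  alpha_obs <- c(truth$alpha$mean * p_alpha, truth$alpha$sd)
  dev_obs <- development_params(dev$w_c, dev$j, dev$mu * p_mu,
                                dev$max_horizon_h)
  wander <- simulate_maturity(rates_obs, alpha_obs, m0_dist, dev_obs, n)
  wander <- wander[wander$reached_wc, c("age_h", "mass_g")]
  wander$diet <- truth$diet
  list(durations = durations, initial_mass = m0, wandering = wander,
       params = list(rates = rates_obs,
                     alpha = alpha_obs, dev = dev_obs, m0_dist = m0_dist,
                     perturb = perturb))
}

#' Two-sample energy-distance permutation test
#'
#' Szekely-Rizzo energy statistic for equality of two multivariate
#' distributions, with a permutation p-value.  Columns are standardised
#' jointly before distances are computed (age and mass live on different
#' scales).  Used by the validation subcommand to detect divergence between
#' predicted and "observed" joint age/mass distributions.
#'
#' @param x,y Numeric matrices (or data frames) with the same columns.
#' @param n_perm Number of permutations (default 199).
#' @param seed Optional integer seed.
#' @return List: `statistic` (energy distance), `p_value`, `n_perm`.
#' @export
energy_test <- function(x, y, n_perm = 199, seed = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y), nrow(x) >= 2, nrow(y) >= 2)
  if (!is.null(seed)) set.seed(seed)
  z <- rbind(x, y)
  z <- scale(z)
  n <- nrow(x); m <- nrow(y); N <- n + m
  D <- as.matrix(dist(z))
  estat <- function(idx) {
    A <- idx; B <- setdiff(seq_len(N), idx)
    2 * mean(D[A, B]) - mean(D[A, A]) - mean(D[B, B])
  }
  obs <- estat(seq_len(n))
  perm <- replicate(n_perm, estat(sample(N, n)))
  list(statistic = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
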