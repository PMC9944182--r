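#' Development parameters of the critical-weight / JH-degradation model
#'
#' `w_c` is the critical weight at which juvenile hormone (JH) begins to
#' degrade; complete degradation triggers the cessation of growth
#' (wandering).  Degradation is the sum of `j` exponential steps of mean
#' `mu` hours, i.e. Gamma(shape `j`, scale `mu`) with mean `j * mu`.
#' Defaults (`w_c = 7` g, `j = 48`, `mu = 1` h) reproduce the ~48 h
#' growth-cessation phase reported for *Manduca sexta* at 25 C.
#'
#' @param w_c Critical weight, grams (> 0).
#' @param j Number of JH degradation steps (integer >= 1).
#' @param mu Mean duration of one step, hours (> 0).
#' @param max_horizon_h Simulation guard: replicates not reaching `w_c` by
#'   this age are returned censored.
#' @return A list of class `development_params`.
#' @export
development_params <- function(w_c = 7, j = 48L, mu = 1, max_horizon_h = 5000) {
  if (w_c <= 0 || mu <= 0 || max_horizon_h <= 0)
    stop("w_c, mu and max_horizon_h must be positive", call. = FALSE)
  j <- as.integer(j)
  if (is.na(j) || j < 1) stop("j must be an integer >= 1", call. = FALSE)
  structure(list(w_c = w_c, j = j, mu = mu, max_horizon_h = max_horizon_h),
            class = "development_params")
}

#' Simulate total feeding times in fixed trial windows
#'
#' Event-driven draws of the occupation time of the feeding state over a
#' window of `Z` hours, starting nonfeeding; the simulation counterpart of
#' [occupation_log_density()], used to assess model fit against observed
#' trial feeding times.
#'
#' @param rates A [switch_rates()] object.
#' @param Z Window length in hours (scalar, or vector of length `n`).
#' @param n Number of replicates.
#' @param seed Optional integer seed.
#' @param start_state State at time 0.
#' @return Numeric vector of `n` total feeding times, hours.
#' @export
simulate_feeding_times <- function(rates, Z = 1, n, seed = NULL,
                                   start_state = c("nonfeeding", "feeding")) {
  rates <- as_switch_rates(rates)
  start_state <- match.arg(start_state)
  stopifnot(n >= 1, all(Z > 0), length(Z) %in% c(1L, as.integer(n)))
  if (!is.null(seed)) set.seed(seed)
  sim_occupation_cpp(as.integer(n), rates$lambda_f, rates$lambda_n,
                     as.numeric(Z), start_state == "feeding")
}

#' Predict mass gain over the 4th instar
#'
#' Each replicate draws an instar duration from `durations_h` (with
#' replacement), simulates switching over that window from a nonfeeding
#' start, draws alpha from the (zero-truncated) normal `alpha_dist`, and
#' returns `alpha * total feeding time`.
#'
#' @param rates A [switch_rates()] object.
#' @param alpha_dist An alpha distribution ([fit_alpha_distribution()] or
#'   `c(mean, sd)`).
#' @param durations_h Pool of instar durations, hours (all > 0).
#' @param n Number of replicates.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` simulated mass gains, grams.
#' @export
simulate_instar4_gain <- function(rates, alpha_dist, durations_h, n,
                                  seed = NULL) {
  rates <- as_switch_rates(rates)
  if (length(durations_h) == 0 || any(!is.finite(durations_h)) ||
      any(durations_h <= 0))
    stop("durations_h must be a non-empty pool of positive durations",
         call. = FALSE)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  # guard the length-1 pool: sample(x, ...) would read a scalar as 1:x
  D <- if (length(durations_h) == 1) rep(durations_h, n)
       else sample(durations_h, n, replace = TRUE)
  W <- sim_occupation_cpp(as.integer(n), rates$lambda_f, rates$lambda_n,
                          as.numeric(D), FALSE)
  sample_alpha(alpha_dist, n) * W
}

#' Simulate the joint age and mass at maturity
#'
#' Full model of 5th-instar development: each replicate draws an initial
#' mass `m0` (normal truncated > 0) and an alpha (normal truncated >= 0),
#' then alternates feeding/nonfeeding from a nonfeeding start, gaining mass
#' at rate alpha while feeding.  When mass first reaches the critical weight
#' `dev$w_c`, JH degradation starts: a Gamma(shape `j`, scale `mu`) duration
#' `G` (equivalently `j` exponential steps) during which switching and
#' growth continue.  At the end of `G` the age (hours since instar start)
#' and mass are recorded.  Individuals starting at or above `w_c` begin
#' degradation at time 0.
#'
#' `mode = "fast"` replaces the event-by-event pre-critical-weight phase by
#' an exact distributional equivalent: the time to accumulate the required
#' feeding time `x_req = (w_c - m0)/alpha` from a nonfeeding start is
#' `x_req + Gamma(K + 1, rate lambda_n)` with `K ~ Poisson(lambda_f x_req)`
#' completed feeding bouts.  The degradation window is always simulated
#' event by event.  `mode = "exact"` runs the full event-driven path
#' (optionally with step-wise JH), and is used to validate the fast mode.
#'
#' @param rates A [switch_rates()] object.
#' @param alpha_dist Alpha distribution (`fit_alpha_distribution()` or
#'   `c(mean, sd)`), truncated at 0 when sampling.
#' @param m0_dist Initial-mass distribution: `c(mean, sd)` in grams,
#'   truncated at 0 when sampling.
#' @param dev A [development_params()] object.
#' @param n Number of replicates.
#' @param seed Optional integer seed.
#' @param mode `"fast"` (default) or `"exact"`; identical distributions.
#' @param stepwise_jh In `"exact"` mode, draw the degradation duration as
#'   `j` explicit exponential steps instead of one Gamma variate.
#' @return A data frame of class `maturity_sample` with columns `replicate`,
#'   `m0_g`, `alpha_g_per_h`, `age_h`, `mass_g`, `reached_wc`.  Censored
#'   replicates (never reached `w_c` within `dev$max_horizon_h`) have `NA`
#'   age and mass.
#' @export
simulate_maturity <- function(rates, alpha_dist, m0_dist,
                              dev = development_params(), n, seed = NULL,
                              mode = c("fast", "exact"),
                              stepwise_jh = FALSE) {
  rates <- as_switch_rates(rates)
  mode <- match.arg(mode)
  stopifnot(inherits(dev, "development_params"), n >= 1,
            is.numeric(m0_dist), length(m0_dist) == 2, m0_dist[2] >= 0)
  a <- as_alpha_distribution(alpha_dist)
  if (a$mean <= 0 && m0_dist[1] < dev$w_c)
    warning("alpha distribution with mean <= 0 below the critical weight: most replicates will be censored",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m0 <- sample_truncated_normal(n, m0_dist[1], m0_dist[2], lower = 0)
  alpha <- sample_alpha(a, n)
  lf <- rates$lambda_f; ln <- rates$lambda_n
  if (mode == "exact") {
    sim <- sim_maturity_cpp(m0, alpha, lf, ln, dev$w_c, dev$j, dev$mu,
                            dev$max_horizon_h, stepwise_jh)
    age <- sim$age_h; mass <- sim$mass_g; reached <- sim$reached_wc
  } else {
    x_req <- ifelse(m0 >= dev$w_c, 0, (dev$w_c - m0) / alpha)  # Inf if alpha=0
    reached <- is.finite(x_req)
    tau <- rep(NA_real_, n)
    ok <- reached
    K <- rpois(sum(ok), lf * x_req[ok])
    tau[ok] <- x_req[ok] + rgamma(sum(ok), shape = K + 1, rate = ln)
    tau[ok][x_req[ok] == 0] <- 0
    cens <- ok & tau > dev$max_horizon_h
    reached[cens] <- FALSE
    G <- rgamma(n, shape = dev$j, scale = dev$mu)
    # during degradation the larva is mid-feeding-bout (it was feeding when
    # it hit w_c), except when it started at or above w_c (nonfeeding start)
    W <- rep(NA_real_, n)
    mid <- reached & m0 < dev$w_c
    top <- reached & m0 >= dev$w_c
    if (any(mid)) W[mid] <- sim_occupation_cpp(sum(mid), lf, ln,
                                               G[mid], TRUE)
    if (any(top)) W[top] <- sim_occupation_cpp(sum(top), lf, ln,
                                               G[top], FALSE)
    age <- ifelse(reached, tau + G, NA_real_)
    mass <- ifelse(reached, pmax(m0, dev$w_c) + alpha * W, NA_real_)
  }
  out <- data.frame(replicate = seq_len(n), m0_g = m0, alpha_g_per_h = alpha,
                    age_h = age, mass_g = mass, reached_wc = reached)
  class(out) <- c("maturity_sample", "data.frame")
  out
}

#' Summarise a joint age/mass-at-maturity sample
#'
#' Marginal statistics plus a 2-D kernel density estimate with
#' highest-density-region (HDR) contours at the requested coverage levels.
#' Bandwidths use the normal-reference rule per axis ([MASS::kde2d()]
#' default).  Degenerate samples (either marginal essentially constant) get
#' marginals only, with a warning, and an empty contour set.
#'
#' @param samples A `maturity_sample` data frame (or any data frame with
#'   `age_h`, `mass_g`, `reached_wc`).
#' @param levels HDR coverage levels, each in (0, 1).
#' @param n_grid Grid size per axis for the KDE.
#' @return A list of class `joint_summary`: `n_used`, `n_censored`,
#'   `marginals` (data frame of mean/sd/quantiles for age and mass),
#'   `levels`, `contours` (per level, a list of polygons with `x` = age,
#'   `y` = mass), and `kde` (the grid).
#' @export
summarize_joint <- function(samples, levels = c(0.5, 0.9), n_grid = 128L) {
  stopifnot(all(c("age_h", "mass_g", "reached_wc") %in% names(samples)))
  ok <- samples$reached_wc & is.finite(samples$age_h) &
    is.finite(samples$mass_g)
  n_cens <- sum(!ok)
  age <- samples$age_h[ok]; mass <- samples$mass_g[ok]
  if (length(age) < 100)
    stop("need at least 100 uncensored samples to summarise", call. = FALSE)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  marg <- data.frame(
    variable = c("age_h", "mass_g"),
    mean = c(mean(age), mean(mass)),
    sd = c(sd(age), sd(mass)),
    rbind(quantile(age, qs), quantile(mass, qs)), check.names = FALSE)
  degenerate <- sd(age) < 1e-10 * max(1, abs(mean(age))) ||
    sd(mass) < 1e-10 * max(1, abs(mean(mass)))
  if (!degenerate && abs(cor(age, mass)) > 1 - 1e-8)
    degenerate <- TRUE                 # samples on a line: KDE ill-posed
  contours <- list(); kde <- NULL
  if (degenerate) {
    warning("degenerate joint sample (a marginal is constant); contours skipped",
            call. = FALSE)
  } else {
    kde <- MASS::kde2d(age, mass, n = n_grid)
    # HDR threshold per level: the density value below which the estimated
    # density at the sample points falls with probability 1 - level
    d_at <- kde_at_points(kde, age, mass)
    thresholds <- quantile(d_at, 1 - levels, names = FALSE)
    contours <- lapply(seq_along(levels), function(i) {
      contourLines(kde$x, kde$y, kde$z, levels = thresholds[i])
    })
    names(contours) <- paste0("hdr_", round(100 * levels))
  }
  structure(list(n_used = length(age), n_censored = n_cens,
                 marginals = marg, levels = levels, contours = contours,
                 kde = kde),
            class = "joint_summary")
}

# bilinear interpolation of a kde2d grid at arbitrary points
kde_at_points <- function(kde, x, y) {
  ix <- findInterval(x, kde$x, all.inside = TRUE)
  iy <- findInterval(y, kde$y, all.inside = TRUE)
  fx <- (x - kde$x[ix]) / diff(kde$x)[1]
  fy <- (y - kde$y[iy]) / diff(kde$y)[1]
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  kde$z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    kde$z[cbind(ix + 1L, iy)] * fx * (1 - fy) +
    kde$z[cbind(ix, iy + 1L)] * (1 - fx) * fy +
    kde$z[cbind(ix + 1L, iy + 1L)] * fx * fy
}

#' Is a point inside an HDR contour set?
#'
#' Utility for split-sample checks of HDR calibration: tests whether points
#' fall inside any polygon of a contour level returned by
#' [summarize_joint()].
#'
#' @param contours One element of `summarize_joint()$contours` (a list of
#'   polygons).
#' @param x,y Point coordinates (age, mass).
#' @return Logical vector.
#' @export
points_in_hdr <- function(contours, x, y) {
  inside <- rep(FALSE, length(x))
  for (poly in contours) {
    inside <- inside | point_in_polygon(x, y, poly$x, poly$y)
  }
  inside
}

# even-odd ray casting
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' @export
print.joint_summary <- function(x, ...) {
  cat(sprintf("joint summary of %d samples (%d censored)\n",
              x$n_used, x$n_censored))
  print(x$marginals, row.names = FALSE)
  invisible(x)
}
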