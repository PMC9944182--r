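test_that("simulate_bouts respects degenerate and seeded cases", {
  # a process that essentially never leaves the nonfeeding state
  s <- simulate_bouts(switch_rates(10, 1e-9), Z = 1, seed = 1)
  expect_equal(nrow(s$bouts), 1L)
  expect_equal(s$bouts$state, "nonfeeding")
  expect_equal(total_feeding_time(s), 0)

  s1 <- simulate_bouts(switch_rates(10.25, 4.93), Z = 1, seed = 42)
  s2 <- simulate_bouts(switch_rates(10.25, 4.93), Z = 1, seed = 42)
  expect_identical(s1$bouts, s2$bouts)

  expect_error(simulate_bouts(switch_rates(10, 5), Z = -1), "positive")
  expect_error(switch_rates(-1, 5), "positive")
  expect_error(switch_rates(Inf, 5), "positive")
})

test_that("completed-bout count matches the renewal-rate oracle", {
  # with both rates 60/h the switch process is Poisson(60) regardless of
  # state, so completed bouts (= switches) average 60 per hour
  set.seed(7)
  n_completed <- replicate(10000, {
    nrow(simulate_bouts(switch_rates(60, 60), Z = 1)$bouts) - 1L
  })
  expect_equal(mean(n_completed), 60, tolerance = 0.3 / 60)
  expect_equal(var(n_completed), 60, tolerance = 0.05)  # Poisson variance
})

test_that("total_feeding_time is exact arithmetic and conserves the window", {
  s <- seq_from_durations(c(600, 1200, 1800), first = "nonfeeding")
  expect_identical(total_feeding_time(s), 1200 / 3600)

  set.seed(11)
  for (i in 1:25) {
    s <- simulate_bouts(switch_rates(runif(1, 1, 80), runif(1, 1, 80)), Z = 1)
    f <- s$bouts$state == "feeding"
    feed <- sum(s$bouts$end_s[f] - s$bouts$start_s[f])
    nonfeed <- sum(s$bouts$end_s[!f] - s$bouts$start_s[!f])
    expect_equal(feed + nonfeed, 3600)
    expect_true(total_feeding_time(s) >= 0 && total_feeding_time(s) <= 1)
  }
})

test_that("bout_sequence validation catches malformed input", {
  expect_error(bout_sequence(c("feeding", "feeding"), c(0, 10), c(10, 3600), 1),
               "alternate")
  expect_error(bout_sequence(c("feeding", "nonfeeding"), c(0, 20), c(10, 3600), 1),
               "contiguous")
  expect_error(bout_sequence("feeding", 0, 1800, 1), "window")
  expect_error(bout_sequence("grazing", 0, 3600, 1), "states")
})

test_that("minimum-bout filter absorbs short bouts into the surrounding state", {
  # 3-s feeding bout between two nonfeeding bouts disappears entirely
  s <- bout_sequence(c("nonfeeding", "feeding", "nonfeeding"),
                     c(0, 100, 103), c(100, 103, 3600), 1)
  out <- apply_min_bout_filter(s, 5)
  expect_equal(nrow(out$bouts), 1L)
  expect_equal(out$bouts$state, "nonfeeding")
  expect_equal(out$bouts$end_s, 3600)

  # nothing shorter than 5 s: identity
  s2 <- seq_from_durations(c(60, 30, 60, 3450))
  expect_identical(apply_min_bout_filter(s2, 5)$bouts, s2$bouts)
})

test_that("filter is idempotent and preserves alternation and duration", {
  set.seed(23)
  for (i in 1:40) {
    s <- random_bout_seq(sample(3:25, 1))
    once <- apply_min_bout_filter(s, 5)
    twice <- apply_min_bout_filter(once, 5)
    expect_identical(once$bouts, twice$bouts)
    expect_identical(once$bouts, filter_reference(s, 5)$bouts)
    validate_ok <- tryCatch({
      boutgrow:::validate_bout_sequence(once); TRUE
    }, error = function(e) FALSE)
    expect_true(validate_ok)
    tot <- sum(once$bouts$end_s - once$bouts$start_s)
    expect_equal(tot, sum(s$bouts$end_s - s$bouts$start_s))
  }
})

test_that("occupation density: atom, continuous limit, domain errors", {
  r <- switch_rates(10.25, 4.93)
  expect_equal(occupation_log_density(0, 1, r), -4.93)
  expect_equal(exp(occupation_log_density(0, 1, r)), 0.007227,
               tolerance = 1e-4)
  # x = Z continuous limit: lambda_n * exp(-lambda_f * Z)
  expect_equal(occupation_log_density(1, 1, r), log(4.93) - 10.25,
               tolerance = 1e-9)
  expect_error(occupation_log_density(1.5, 1, r), "\\[0, Z\\]")
  expect_error(occupation_log_density(-0.1, 1, r), "\\[0, Z\\]")
})

test_that("occupation density normalizes to 1 and stays finite at huge q", {
  for (p in list(c(10.25, 4.93), c(56.22, 24.36), c(1, 1))) {
    r <- switch_rates(p[1], p[2])
    atom <- exp(occupation_log_density(0, 1, r))
    I <- integrate(function(x) exp(occupation_log_density(x, 1, r)),
                   0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(atom + I, 1, tolerance = 1e-6)
  }
  # q = 2 sqrt(a b x y) ~ 1e4 must not overflow
  r_big <- switch_rates(2e4, 1e4)
  ld <- occupation_log_density(seq(0.05, 0.95, by = 0.05), 1, r_big)
  expect_true(all(is.finite(ld)))
})

test_that("R and C++ density implementations agree", {
  xs <- c(1e-8, seq(0.001, 0.999, length.out = 400), 1 - 1e-8)
  for (p in list(c(10.25, 4.93), c(59.43, 37.99), c(500, 200))) {
    d_r <- occupation_log_density(xs, 1, switch_rates(p[1], p[2]))
    d_c <- boutgrow:::occ_logpdf_cpp(xs, 1, p[1], p[2])
    expect_equal(d_r, d_c, tolerance = 1e-5)
  }
})

test_that("analytic occupation distribution matches simulation (smoke scale)", {
  r <- switch_rates(10.25, 4.93)
  W <- simulate_feeding_times(r, 1, 2e5, seed = 5)
  expect_lt(ks_occupation(W, 1, r), 0.01)
  expect_equal(mean(W == 0), exp(-4.93), tolerance = 0.15)
  # feeding-start reflection also normalizes and matches simulation
  atomZ <- exp(-r$lambda_f * 1)
  I <- integrate(function(x)
    exp(occupation_log_density(x, 1, r, start_state = "feeding")),
    0, 1, rel.tol = 1e-10)$value
  expect_equal(I + atomZ, 1, tolerance = 1e-6)
  Wf <- simulate_feeding_times(r, 1, 1e5, seed = 6, start_state = "feeding")
  expect_lt(ks_occupation(Wf, 1, r, start_state = "feeding"), 0.015)
})

test_that("expected feeding fraction: limits, example value, simulation", {
  r_eq <- switch_rates(12, 12)
  expect_equal(expected_feeding_fraction(r_eq, 1e6), 0.5, tolerance = 1e-6)
  expect_lt(expected_feeding_fraction(r_eq, 1e-9), 1e-6)
  expect_error(expected_feeding_fraction(r_eq, 0), "positive")

  r <- switch_rates(10.25, 4.93)
  f24 <- expected_feeding_fraction(r, 24)
  expect_equal(f24, 4.93 / 15.18, tolerance = 2e-3 / 0.32)
  expect_equal(f24, transient_fraction_oracle(10.25, 4.93, 24),
               tolerance = 1e-12)
  # simulation cross-check of the transient mean over 1 h
  W <- simulate_feeding_times(r, 1, 1e5, seed = 9)
  se <- sd(W) / sqrt(length(W))
  expect_lt(abs(mean(W) - expected_feeding_fraction(r, 1)), 3 * se)
})

test_that("stationary fraction and long-window consistency", {
  expect_equal(stationary_feeding_fraction(switch_rates(3, 3)), 0.5)
  expect_equal(stationary_feeding_fraction(switch_rates(10.25, 4.93)),
               0.32477, tolerance = 1e-4)
  # relaxation term decays like pi/(r T): ~3e-10 at T = 1e8
  r <- switch_rates(7, 3)
  expect_equal(expected_feeding_fraction(r, 1e8),
               stationary_feeding_fraction(r), tolerance = 1e-9)
})
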