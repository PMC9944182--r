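# boutgrow

Feeding-bout dynamics and insect growth to maturity.

`boutgrow` is for quantitative ecologists and physiologists who record
larval feeding behaviour as alternating feeding/nonfeeding bouts (an
ethogram from, say, a 1-h trial) and want to connect those records to life
history: how fast larvae switch between states on different diets, how much
mass a feeding hour buys, and what the resulting joint distribution of age
and mass at maturity looks like. It was built around the biology of
*Manduca sexta* larvae on hosts of differing quality (artificial diet,
tobacco, devil's claw), but nothing ties it to that system.

## The model

Behaviour is a two-state telegraph process: exponential bouts, rate
λ_f for leaving feeding and λ_n for leaving nonfeeding (switches/hour).
Within a trial window of length *Z* starting nonfeeding, the total feeding
time *W* has an atom P(W = 0) = exp(−λ_n Z) and, for 0 < x < Z
(y = Z − x, q = 2√(λ_n λ_f x y)),

    f(x) = exp(−λ_f x − λ_n y) [ λ_n I0(q) + √(λ_n λ_f y/x) I1(q) ]

with I0, I1 modified Bessel functions. Per diet-by-instar group, (λ_f, λ_n)
is estimated by maximising the product of these densities over trials, with
90% percentile-bootstrap intervals from resampling whole trials; groups
differ significantly when intervals do not overlap. Mass gain per feeding
hour (α, g/h) is estimated from paired weighings divided by expected
feeding time, and development couples the same switching process to the
critical-weight model: growth at rate α while feeding until mass reaches
w_c (7 g), then a Gamma(j = 48, μ = 1 h) juvenile-hormone degradation
period — during which switching and growth continue — ending in wandering.

## Worked example

Simulate a feeding-trial campaign (200 individuals, 1-h trials, switch
times rounded to the second, 5-s minimum-bout filter), refit it, and
estimate α:

```r
library(boutgrow)

truth <- group_truth("diet", 4, switch_rates(10.25, 4.93), c(0.04, 0.02), 200)
bouts <- generate_trials(truth, seed = 1)
f <- tempfile(fileext = ".csv"); write_bout_log(bouts, f)
log <- read_bout_log(f)

bootstrap_rates(log$trials, n_boot = 10000, seed = 1)
#> lambda_f = 11.59 (9.947, 13.94), lambda_n = 5.02 (4.346, 5.956)
#>   [90% percentile bootstrap, 10000 resamples, 0 failed]

rec <- generate_mass_records(truth, seed = 2)
fit_alpha_distribution(estimate_alpha(rec, switch_rates(11.59, 5.02)))
#> alpha ~ Normal(0.04565, 0.02124) g/h  (n = 200)
```

The generating rates (10.25, 4.93) and α mean (0.04 g/h) sit inside the
intervals: at 200 trials the estimator recovers the truth; at the real
study's 11–19 individuals per group expect much wider, skewed intervals
(see the methods vignette).

Simulate the joint age/mass-at-maturity distribution for 5th instars on
artificial diet and summarise it:

```r
s <- simulate_maturity(switch_rates(16.85, 11.05), c(0.15, 0.04),
                       c(1.8, 0.4), development_params(), n = 100000,
                       seed = 1)
summarize_joint(s)
#> joint summary of 99997 samples (3 censored)
#>  variable       mean         sd        5%        25%        50%       75%       95%
#>     age_h 144.225124 46.2476034 104.51979 121.032490 136.071521 156.46771 207.62866
#>    mass_g   9.855786  0.8842739   8.50263   9.242603   9.799455  10.41042  11.40134
```

Mean age ≈ 144 h after the 5th-instar molt and mean mass ≈ 9.9 g at
wandering — the ~2.9 g overshoot past the 7 g critical weight is feeding
during the ~48 h hormone-degradation window. The same pipeline is scriptable
via the CLI (`exec/boutgrow`): `generate`, `fit`, `bootstrap`, `alpha`,
`simulate-trials`, `simulate-instar4`, `simulate-maturity`, `validate`.

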