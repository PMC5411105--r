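test_that("the diet signal follows the two-phase trajectory", {
  p <- weaning_params(1.7, 2.8, 1.0, 7.4, 10.91)
  expect_equal(diet_d15N(p, 0), 11.91)
  expect_equal(diet_d15N(p, 1.7), 11.91)
  expect_equal(diet_d15N(p, 2.8), 7.4)
  expect_equal(diet_d15N(p, 5), 7.4)
  expect_equal(diet_d15N(p, (1.7 + 2.8) / 2), (11.91 + 7.4) / 2)
  expect_error(weaning_params(2.8, 1.7, 1, 7.4, 10.91), "t1 <= t2")
  expect_error(weaning_params(1, 2, -0.5, 7.4, 10.91), "nonnegative")
  # abrupt weaning: step function
  ps <- weaning_params(2, 2, 1, 7.4, 10.91)
  expect_equal(diet_d15N(ps, c(1.99, 2, 2.01)), c(11.91, 7.4, 7.4))
})

test_that("the turnover rate declines from r0 to the adult asymptote", {
  tm <- turnover_model()
  expect_equal(turnover_rate(tm, 0), 2.5)
  t <- seq(0, 20, by = 0.5)
  r <- turnover_rate(tm, t)
  expect_true(all(diff(r) < 0))
  expect_lt(abs(turnover_rate(tm, 100) - 0.1), 1e-6)
  expect_error(turnover_model(r0 = 0.05, r_inf = 0.1), "r0 >= r_inf")
})

test_that("the trajectory matches the closed form for constant diet/rate", {
  # constant rate via r0 = r_inf; constant diet via t1 = t2 = 0
  r <- 0.7
  tm <- turnover_model(r0 = r, r_inf = r, tau = 1)
  D <- 6.5
  y0 <- 10.91
  p <- weaning_params(0, 0, 0, D, y0)
  got <- collagen_trajectory(p, tm, c(0.5, 1, 2), ode_step = 0.01)
  want <- D + (y0 - D) * exp(-r * c(0.5, 1, 2))
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("the trajectory matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- weaning_params(1.2, 2.6, 1.3, 6.8, 10.91)
  tm <- turnover_model()
  ages <- c(0.25, 0.8, 1.5, 2.2, 3.1, 4.4, 5.5)
  got <- collagen_trajectory(p, tm, ages, ode_step = 0.01)
  sol <- deSolve::ode(y = c(y = 10.91), times = c(0, ages),
                      func = function(t, y, parms)
                        list(turnover_rate(tm, t) * (diet_d15N(p, t) - y)),
                      parms = NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-10)
  expect_lt(max(abs(got - sol[-1, "y"])), 1e-4)
})

test_that("fast turnover makes collagen track the diet signal", {
  tm <- turnover_model(r0 = 1000, r_inf = 1000, tau = 1)
  p <- weaning_params(0.3, 1.3, 1.5, 7, 11)
  ages <- seq(0.1, 1.3, by = 0.05)
  got <- collagen_trajectory(p, tm, ages, ode_step = 5e-4)
  expect_lt(max(abs(got - diet_d15N(p, ages))), 1e-2)
})

test_that("the trajectory rises above the female mean, then falls below", {
  p <- weaning_params(1.7, 2.8, 1.0, 7.4, 10.91)
  tm <- turnover_model()
  ages <- seq(0, 5.5, by = 0.05)
  y <- collagen_trajectory(p, tm, ages, ode_step = 0.005)
  expect_gt(max(y[ages <= 1.7]) - 10.91, 0.5)   # infancy enrichment imprints
  peak_age <- ages[which.max(y)]
  expect_lt(peak_age, 2.8)                       # peaks before weaning ends
  expect_lt(y[length(y)], 10.91)                 # depleted after weaning
  # no overshoot: bounded by initial value and diet extremes
  lo <- min(10.91, diet_d15N(p, ages))
  hi <- max(10.91, diet_d15N(p, ages))
  expect_true(all(y >= lo - 1e-9 & y <= hi + 1e-9))
})

test_that("no overshoot across random parameter draws", {
  set.seed(12)
  tm <- turnover_model()
  for (i in 1:20) {
    t1 <- runif(1, 0, 3)
    p <- weaning_params(t1, t1 + runif(1, 0, 3), runif(1, 0, 3),
                        runif(1, 3, 11), 10.91)
    ages <- sort(runif(8, 0, 6))
    y <- collagen_trajectory(p, tm, ages, ode_step = 0.02)
    lo <- min(10.91, p$d15N_wnfood, 10.91 + p$enrich)
    hi <- max(10.91, p$d15N_wnfood, 10.91 + p$enrich)
    expect_true(all(y >= lo - 1e-9 & y <= hi + 1e-9))
  }
})

test_that("halving the step changes the trajectory negligibly", {
  p <- weaning_params(1.7, 2.8, 1.0, 7.4, 10.91)
  tm <- turnover_model()
  ages <- c(0.2, 0.9, 1.8, 2.7, 3.6, 5.4)
  a <- collagen_trajectory(p, tm, ages, ode_step = 0.02)
  b <- collagen_trajectory(p, tm, ages, ode_step = 0.01)
  expect_lt(max(abs(a - b)), 1e-4)
})

test_that("trajectory input validation", {
  p <- weaning_params(1, 2, 1, 7, 11)
  expect_error(collagen_trajectory(p, turnover_model(), c(2, 1)),
               "nondecreasing")
  expect_error(collagen_trajectory(p, turnover_model(), c(-1, 1)),
               "nonnegative")
})

test_that("the ABC distance is the root mean square", {
  expect_equal(warn_distance(c(1, 1), c(0, 2)), 1)
  expect_equal(warn_distance(1:5, 1:5), 0)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10); perm <- sample(10)
  expect_equal(warn_distance(a[perm], b[perm]), warn_distance(a, b))
  expect_error(warn_distance(1:3, 1:4), "equal")
})

test_that("ABC configuration guards its invariants", {
  expect_error(abc_config(accept_fraction = 0.2), "accept_fraction")
  expect_error(abc_config(priors = list(t1 = c(1, 1), dt = c(0, 5),
                                        enrich = c(0, 4),
                                        wnfood = c(2, 12))),
               "degenerate")
})

test_that("ABC results are bitwise reproducible for a fixed seed", {
  cohort <- simulate_juvenile_cohort(
    12, weaning_params(1, 2.5, 1.2, 7, 10.91), seed = 5)
  ages <- cohort$age_low_years
  f1 <- fit_warn_abc(ages, cohort$d15N, 10.91,
                     config = test_abc_config(33, n_sims = 1e4))
  f2 <- fit_warn_abc(ages, cohort$d15N, 10.91,
                     config = test_abc_config(33, n_sims = 1e4))
  expect_identical(f1$accepted, f2$accepted)
  expect_identical(f1$mde, f2$mde)
})

test_that("ABC recovers known weaning ages from a synthetic cohort", {
  truth <- weaning_params(1.5, 3.0, 1.2, 7.0, 10.91)
  cohort <- simulate_juvenile_cohort(31, truth, obs_noise_sd = 1.5,
                                     seed = 17)
  f <- fit_warn_abc(cohort$age_low_years, cohort$d15N, 10.91,
                    config = abc_config(n_sims = 1e5,
                                        accept_fraction = 0.002,
                                        rng_seed = 17, ode_step = 0.05))
  expect_lt(abs(f$mde["t1"] - 1.5), 0.5)
  # the weaning end is weakly identified for a single cohort (slow
  # post-weaning turnover); its credible interval must cover the truth
  expect_true(f$ci95["t2", 1] <= 3.0 && 3.0 <= f$ci95["t2", 2])
  expect_true(f$ci95["t1", 1] <= f$mde["t1"] &&
                f$mde["t1"] <= f$ci95["t1", 2])
  expect_true(all(f$accepted$t1 <= f$accepted$t2))
})

test_that("a flat cohort at the female mean drives enrichment toward zero", {
  set.seed(6)
  ages <- sort(runif(20, 0.1, 5))
  d15N <- rnorm(20, 10.91, 0.05)
  f <- fit_warn_abc(ages, d15N, 10.91, config = test_abc_config(6))
  expect_lt(median(f$accepted$enrich), 1)
  expect_gt(mean(f$accepted$enrich < 0.75), 0.5)
})

test_that("the joint MDE matches a known truncated bivariate normal", {
  set.seed(99)
  n <- 1e5
  acc <- data.frame(t1 = rnorm(n, 1.5, 0.3), t2 = rnorm(n, 2.5, 0.3),
                    enrich = rnorm(n, 1, 0.2), wnfood = rnorm(n, 7, 0.5))
  acc <- acc[acc$t1 <= acc$t2, ]
  d <- posterior_density_mde(acc)
  cell <- c(diff(d$density$x[1:2]), diff(d$density$y[1:2]))
  # grid argmax of a smoothed near-flat peak carries discretization plus
  # KDE sampling noise: allow two grid cells around the analytic mode
  expect_lt(abs(d$mde["t1"] - 1.5), 2 * cell[1] + 1e-9)
  expect_lt(abs(d$mde["t2"] - 2.5), 2 * cell[2] + 1e-9)
  expect_lt(abs(d$mde["enrich"] - 1), 0.05)
  expect_equal(unname(d$ci95["wnfood", ]),
               unname(quantile(acc$wnfood, c(0.025, 0.975))))
})

test_that("degenerate accepted draws give a point MDE with zero-width CI", {
  acc <- data.frame(t1 = rep(1.2, 300), t2 = rep(2.2, 300),
                    enrich = rep(0.7, 300), wnfood = rep(7.7, 300))
  d <- posterior_density_mde(acc)
  expect_equal(unname(d$mde), c(1.2, 2.2, 0.7, 7.7))
  expect_equal(unname(d$ci95[, "lower"]), unname(d$ci95[, "upper"]))
  expect_error(posterior_density_mde(acc[1:100, ]), "200")
})
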