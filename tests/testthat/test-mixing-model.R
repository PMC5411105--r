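test_that("mixture mean is the concentration-weighted adjusted average", {
  srcs <- sources_fixture()
  expect_equal(mixture_mean(c(1, 0, 0, 0), srcs, "N"), 7.39 + 4.42)
  expect_equal(mixture_mean(c(0, 1, 0, 0), srcs, "C"), -22.45 + 4.40)
  # equal concentrations: weights cancel, plain average
  eq <- srcs
  eq$conc_N <- 2
  expect_equal(mixture_mean(rep(0.25, 4), eq, "N"),
               mean(eq$mu_N + eq$frac_N))
})

test_that("mixture mean is invariant to rescaling all concentrations", {
  srcs <- sources_fixture()
  set.seed(1)
  for (i in 1:10) {
    p <- as.vector(rmultinom(1, 100, rep(1, 4))) / 100
    scaled <- srcs
    scaled$conc_N <- scaled$conc_N * 7.3
    scaled$conc_C <- scaled$conc_C * 0.21
    expect_equal(mixture_mean(p, scaled, "N"), mixture_mean(p, srcs, "N"))
    expect_equal(mixture_mean(p, scaled, "C"), mixture_mean(p, srcs, "C"))
  }
})

test_that("off-simplex proportions are rejected", {
  srcs <- sources_fixture()
  expect_error(mixture_mean(c(0.5, 0.5, 0.5, -0.5), srcs, "N"),
               "nonnegative")
  expect_error(mixture_mean(c(0.5, 0.2, 0.2, 0.2), srcs, "N"), "sum to 1")
  expect_error(mixture_variance(c(1, 1), srcs, "N"), "length")
})

test_that("mixture variance propagates source and fractionation SDs", {
  srcs <- sources_fixture()
  expect_equal(mixture_variance(c(1, 0, 0, 0), srcs, "N", 0),
               1.19^2 + 0.11^2)
  # all source SDs zero: only the residual remains
  z <- srcs
  z[c("sd_N", "sd_frac_N")] <- 0
  expect_equal(mixture_variance(c(0.3, 0.3, 0.2, 0.2), z, "N", 1.7), 1.7^2)
  # halving mass between two identical sources halves the source term
  two <- toy_sources()
  two$mu_N <- c(5, 5)
  v_one <- mixture_variance(c(1, 0), two, "N", 0)
  v_half <- mixture_variance(c(0.5, 0.5), two, "N", 0)
  expect_equal(v_half, 0.5 * v_one)
})

test_that("single-source mixtures reduce to the adjusted source values", {
  one <- sources_fixture()[1, ]
  expect_equal(mixture_mean(1, one, "N"), one$mu_N + one$frac_N)
  expect_equal(mixture_variance(1, one, "N", 0.5),
               one$sd_N^2 + one$sd_frac_N^2 + 0.25)
  expect_error(fit_mixing(data.frame(d15N = 10, d13C = -19), one),
               "two sources")
})

test_that("the log posterior matches a term-by-term oracle", {
  srcs <- sources_fixture()
  cons <- data.frame(d15N = c(10.2, 11.7, 9.4), d13C = c(-17.1, -15.8, -18.9))
  p <- c(0.55, 0.2, 0.15, 0.1)
  rsd <- c(0.8, 1.3)
  cfg <- mixing_config()
  # independent re-evaluation, written out longhand
  oracle <- 0
  for (j in 1:2) {
    q <- if (j == 1) srcs$conc_N else srcs$conc_C
    mu_k <- if (j == 1) srcs$mu_N + srcs$frac_N else srcs$mu_C + srcs$frac_C
    s2_k <- if (j == 1) srcs$sd_N^2 + srcs$sd_frac_N^2
            else srcs$sd_C^2 + srcs$sd_frac_C^2
    x <- if (j == 1) cons$d15N else cons$d13C
    w <- p * q / sum(p * q)
    mu <- sum(w * mu_k)
    v <- sum(w^2 * s2_k) + rsd[j]^2
    for (i in seq_along(x))
      oracle <- oracle - 0.5 * log(2 * pi * v) - (x[i] - mu)^2 / (2 * v)
  }
  oracle <- oracle + sum(dnorm(rsd, 0, cfg$residual_sd_prior_scale,
                               log = TRUE) + log(2))  # Dirichlet(1) adds 0
  expect_equal(mixing_log_posterior(p, rsd, cons, srcs, cfg), oracle)
  expect_error(mixing_log_posterior(p, c(0, 1), cons, srcs, cfg), "positive")
})

test_that("a symmetric two-source problem has a symmetric posterior", {
  two <- toy_sources()
  two$mu_C <- c(-15, -15)
  cons <- data.frame(d15N = 10, d13C = -15)  # midpoint on N, neutral on C
  lp1 <- mixing_log_posterior(c(0.3, 0.7), c(1, 1), cons, two)
  lp2 <- mixing_log_posterior(c(0.7, 0.3), c(1, 1), cons, two)
  expect_equal(lp1, lp2)
})

test_that("the sampler is deterministic given its seed", {
  srcs <- sources_fixture()
  cons <- simulate_mixture_consumers(c(0.6, 0.2, 0.1, 0.1), srcs, 12,
                                     residual_sds = c(0.5, 0.5), seed = 3)
  f1 <- suppressWarnings(fit_mixing(cons, srcs, test_mixing_config(9)))
  f2 <- suppressWarnings(fit_mixing(cons, srcs, test_mixing_config(9)))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$mode_pct, f2$mode_pct)
  f3 <- suppressWarnings(fit_mixing(cons, srcs, test_mixing_config(10)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retained draws always lie on the simplex", {
  srcs <- sources_fixture()
  cons <- simulate_mixture_consumers(c(0.4, 0.3, 0.2, 0.1), srcs, 15,
                                     residual_sds = c(0.5, 0.5), seed = 5)
  f <- suppressWarnings(fit_mixing(cons, srcs, test_mixing_config(11)))
  expect_true(all(f$draws >= 0))
  expect_true(all(abs(rowSums(f$draws) - 1) < 1e-8))
  expect_true(all(f$lci_pct <= f$mode_pct & f$mode_pct <= f$hci_pct))
})

test_that("known mixture proportions are recovered", {
  srcs <- sources_fixture()
  truth <- c(0.7, 0.1, 0.1, 0.1)
  cons <- simulate_mixture_consumers(truth, srcs, 50,
                                     residual_sds = c(0.3, 0.3), seed = 21)
  f <- suppressWarnings(fit_mixing(cons, srcs, test_mixing_config(21)))
  expect_true(all(abs(colMeans(f$draws) - truth) <= 0.1))
})

test_that("duplicate sources leave only their sum identified", {
  three <- data.frame(name = c("milk", "plantA", "plantB"),
                      mu_N = c(12, 4, 4), sd_N = 1, mu_C = c(-14, -20, -20),
                      sd_C = 1, conc_N = c(1.6, 1.1, 1.1), sd_conc_N = 0,
                      conc_C = c(49, 41, 41), sd_conc_C = 0,
                      frac_N = 0, sd_frac_N = 0, frac_C = 0, sd_frac_C = 0)
  cons <- simulate_mixture_consumers(c(0.5, 0.25, 0.25), three, 40,
                                     residual_sds = c(0.3, 0.3), seed = 8)
  f <- suppressWarnings(fit_mixing(cons, three, test_mixing_config(8)))
  s <- f$draws[, 2] + f$draws[, 3]
  # the sum is far better constrained than the individual proportions
  expect_lt(sd(s), 0.6 * sd(f$draws[, 2]))
  expect_lt(abs(mean(s) - 0.5), 0.1)
})

test_that("posterior mode and interval handle point masses and boundaries", {
  expect_equal(posterior_mode_ci(rep(0.4, 150)),
               c(mode = 40, lci = 40, hci = 40))
  expect_error(posterior_mode_ci(rep(0.4, 99)), "100")
  expect_error(posterior_mode_ci(c(rep(0.5, 120), 1.2)), "0, 1")
  set.seed(4)
  piled <- rbeta(5000, 0.4, 8)  # heavy pile near zero
  mci <- posterior_mode_ci(piled)
  expect_lte(mci["mode"], 10)
  expect_equal(unname(mci["lci"]), 0)
  expect_true(mci["lci"] <= mci["mode"] && mci["mode"] <= mci["hci"])
})

test_that("the KDE mode matches the analytic Beta mode", {
  set.seed(7)
  draws <- rbeta(1e5, 2, 5)
  mci <- posterior_mode_ci(draws)
  expect_lt(abs(mci["mode"] / 100 - 0.2), 0.02)
  expect_lt(abs(mci["lci"] / 100 - qbeta(0.025, 2, 5)), 0.015)
  expect_lt(abs(mci["hci"] / 100 - qbeta(0.975, 2, 5)), 0.015)
})
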