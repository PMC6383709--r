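test_that("the Gaussian fitness curve matches closed forms and symmetry", {
  expect_equal(fitness_curve(0.3, A = 2.2, lambda = 0.3, sigma = 0.5), 2.2)
  expect_equal(fitness_curve(1, 1, 0, 1), exp(-1))
  # flat-line limit allowed by the wide sigma prior
  z <- fitness_curve(seq(-2, 2, by = 0.1), A = 5, lambda = 0, sigma = 100)
  expect_true(all(z >= 4.992 & z <= 5))
  # symmetry in (x - lambda)
  x <- rnorm(20)
  expect_equal(fitness_curve(x, 1.5, 0.4, 0.7),
               fitness_curve(2 * 0.4 - x, 1.5, 0.4, 0.7))
  expect_error(fitness_curve(0, 1, 0, -1), "sigma")
})

test_that("the quadratic pretest gates optimum fitting", {
  set.seed(11)
  n <- 1000
  d <- tibble::tibble(lay_z = rnorm(n), season = sample(1:10, n, TRUE))
  d$y <- rpois(n, fitness_curve(d$lay_z, 1.5, -0.9, 0.6))
  pre <- suppressMessages(quadratic_pretest(d, "y", family = "poisson"))
  expect_true(pre$supported)
  expect_gt(pre$delta_aic, 2)

  d$y_flat <- rpois(n, 1)
  pre_flat <- suppressMessages(
    quadratic_pretest(d, "y_flat", family = "poisson"))
  expect_false(pre_flat$supported)
})

test_that("monotone log-linear data rarely support a quadratic term", {
  wins <- 0
  for (r in 1:10) {
    set.seed(100 + r)
    n <- 600
    d <- tibble::tibble(lay_z = rnorm(n), season = sample(1:8, n, TRUE))
    d$y <- rpois(n, exp(0.2 + 0.4 * d$lay_z))
    pre <- suppressMessages(quadratic_pretest(d, "y", family = "poisson"))
    if (!pre$supported) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("optimum fit recovers parameters and reports day-scale optima", {
  d <- simulate_optimum_data(n = 1400, seed = 21)
  attr(d$x, "center") <- 60
  attr(d$x, "scale") <- 28
  fit <- fit_optimum(d, family = "poisson", A_max = 5, chains = 2,
                     n_iter = 8000, thin = 5, burnin = 2500, seed = 31,
                     min_total_ess = 0)
  td <- tidy(fit)
  get <- function(p) td[td$term == p, ]
  expect_gt(get("mu")$upper, -1.15)
  expect_lt(get("mu")$lower, -0.65)
  expect_true(get("A")$lower < 1.5 && get("A")$upper > 1.5 * 0.85)
  expect_true(get("sigma")$lower < 0.75 && get("sigma")$upper > 0.5)
  s <- optimum_summary(fit)
  expect_equal(s$median_day, 60 + 28 * s$median)
  expect_match(s$date_label, "[A-Z][a-z]{2}")
  expect_equal(nrow(per_year_optima(fit)), 16)
  # binomial invariant: all latent Z strictly inside (0, 1) when A_max = 1
  expect_true(all(fit$draws[, "A"] > 0 & fit$draws[, "A"] < 5))
})

test_that("binomial-family fits keep the latent curve inside (0,1)", {
  d <- simulate_optimum_data(n = 500, A = 0.7, family = "binomial",
                             trials = 4, seed = 22)
  fit <- fit_optimum(d, family = "binomial", A_max = 1, chains = 2,
                     n_iter = 4000, thin = 4, burnin = 1000, seed = 5,
                     min_total_ess = 0)
  expect_true(all(fit$draws[, "A"] > 0 & fit$draws[, "A"] < 1))
  z_max <- fit$draws[, "A"]  # peak of the curve per draw
  expect_true(all(z_max < 1))
})

test_that("a temperature cue on the optimum is detected when present", {
  # the per-year sample is small (16 optima), so aggregate over seeded
  # replicates: the sign must always be recovered and the slope clearly
  # supported in most replicates
  pm <- med <- numeric(5)
  for (r in 1:5) {
    set.seed(400 + r)
    theta <- as.numeric(scale(rnorm(16, 0, 1)))
    d <- simulate_optimum_data(n = 1400, B = -0.5, theta = theta,
                               seed = 500 + r)
    fit <- fit_optimum_with_cue(
      d, cue = stats::setNames(theta, 1:16), chains = 2, n_iter = 6000,
      thin = 5, burnin = 2000, seed = 6, min_total_ess = 0)
    pm[r] <- fit$cue_slope$pmcmc
    med[r] <- fit$cue_slope$median
  }
  expect_true(all(med < 0))
  expect_gte(sum(pm < 0.05), 4)

  d <- simulate_optimum_data(n = 100, B = -0.5,
                             theta = rep(0, 16), seed = 1)
  expect_error(
    fit_optimum_with_cue(d, cue = stats::setNames(rep(0, 10), 1:10),
                         chains = 1, n_iter = 200, burnin = 10,
                         min_total_ess = 0),
    "cue missing")
})

test_that("pMCMC is the two-sided posterior sign test", {
  expect_equal(pmcmc(c(0.2, 0.5, 1.1)), 0)
  set.seed(12)
  sym <- rnorm(20000)
  expect_gt(pmcmc(sym), 0.9)
  expect_lte(pmcmc(sym), 1)
})

test_that("posterior predictive checks localise the observed zero fraction", {
  d <- simulate_optimum_data(n = 800, seed = 24)
  fit <- fit_optimum(d, family = "poisson", chains = 2, n_iter = 5000,
                     thin = 5, burnin = 1500, seed = 7, min_total_ess = 0)
  ppc <- posterior_predictive_check(fit, n_rep = 400, seed = 1)
  expect_equal(length(ppc$rep_zero_frac), 400)
  # self-consistency: data generated from the model sit centrally
  expect_gt(ppc$quantile, 0.025)
  expect_lt(ppc$quantile, 0.975)

  # zero inflation: with counts kept high (laying near the optimum), an
  # extra 20% of zeros cannot be absorbed by the Poisson layer
  d_hi <- simulate_optimum_data(n = 800, A = 4, mu = 0, sigma = 1.2,
                                x_mean = 0, seed = 26)
  set.seed(25)
  d_hi$y[sample(nrow(d_hi), 0.2 * nrow(d_hi))] <- 0
  fit_zi <- fit_optimum(d_hi, family = "poisson", A_max = 5, chains = 2,
                        n_iter = 5000, thin = 5, burnin = 1500, seed = 8,
                        min_total_ess = 0)
  ppc_zi <- posterior_predictive_check(fit_zi, n_rep = 400, seed = 2)
  expect_gt(mean(ppc_zi$observed_zero_frac > ppc_zi$rep_zero_frac), 0.975)
})

test_that("the lay-date mode tracks symmetry and skew", {
  set.seed(13)
  sym <- rnorm(5000, 60, 10)
  m <- trait_mode(sym)
  expect_lt(abs(m$mode_day - mean(sym)), 2)
  skew <- 40 + rlnorm(5000, 3, 0.5)
  expect_lt(trait_mode(skew)$mode_day, mean(skew))
  expect_warning(trait_mode(rnorm(20)), "fewer than 50")
})
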