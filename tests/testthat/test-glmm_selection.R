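test_that("age design variants encode hinges and indicators correctly", {
  ages <- c(1, 2, 4, 6, 9)
  d26 <- build_age_design(ages, "break2_6")
  expect_equal(d26[, "age_over2"], pmax(0, ages - 2))
  expect_equal(d26[3, "age_over2"], 2, ignore_attr = TRUE)
  expect_equal(d26[3, "age_over6"], 0, ignore_attr = TRUE)
  expect_equal(d26[5, "age_over6"], 3, ignore_attr = TRUE)

  fy <- build_age_design(ages, "firstyear_plus_break")
  expect_equal(fy[, "first_year"], c(1, 0, 0, 0, 0))

  pt <- build_age_design(ages, "per_transition")
  expect_equal(ncol(pt), max(ages) - 1)
  # rank equals the number of distinct transitions present in the data
  present <- sum(vapply(seq_len(max(ages) - 1), function(k)
    any(ages >= k + 1), logical(1)))
  expect_equal(qr(pt)$rank, length(unique(ages)) - 1)
  expect_error(build_age_design(c(0, 2), "linear"), ">= 1")
})

test_that("AIC arithmetic and its difference property hold", {
  expect_equal(aic(0, 3), 6)
  expect_equal(aic(-100, 5), 210)
  # delta-AIC invariant to a shared log-likelihood shift
  expect_equal(aic(-10 + 7, 2) - aic(-12 + 7, 4),
               aic(-10, 2) - aic(-12, 4))
})

test_that("mixed models recover degenerate and closed-form limits", {
  set.seed(1)
  n <- 400
  d <- tibble::tibble(
    x = rnorm(n), g = factor(rep(1:20, each = n / 20)),
    y = 2 + 1.5 * rnorm(n) + 0.8 * rnorm(n)[1] * 0 + 0.5 * rnorm(n)
  )
  d$y <- 2 + 0.7 * d$x + rnorm(n)  # no group effect at all
  fit <- suppressMessages(fit_mixed_model(d, "y", "x", "g", "gaussian"))
  ols <- lm(y ~ x, data = d)
  expect_lt(abs(fit$estimates$estimate[2] - coef(ols)[["x"]]), 1e-3)
  expect_lt(fit$varcomp$variance[fit$varcomp$group == "g"], 0.05)

  # Poisson intercept-only: intercept = log of the mean
  set.seed(2)
  dp <- tibble::tibble(y = rpois(2000, 3), g = factor(rep(1:10, 200)))
  fp <- fit_mixed_model(dp, "y", character(), "g", "poisson")
  expect_lt(abs(fp$estimates$estimate[1] - log(mean(dp$y))), 0.05)
})

test_that("binomial slope is recovered on synthetic data", {
  set.seed(3)
  n <- 5000
  d <- tibble::tibble(x = rnorm(n), g = factor(rep(1:25, each = n / 25)))
  eta <- -0.5 + 1.5 * d$x + rnorm(25, 0, 0.3)[as.integer(d$g)]
  d$y <- rbinom(n, 1, plogis(eta))
  fit <- fit_mixed_model(d, "y", "x", "g", "binomial")
  est <- fit$estimates[fit$estimates$term == "x", ]
  expect_lt(abs(est$estimate - 1.5), 2 * est$se)
})

test_that("stepwise AIC keeps true predictors and drops noise", {
  set.seed(4)
  n <- 2000
  d <- tibble::tibble(
    strong = rnorm(n), noise = rnorm(n),
    g = factor(rep(1:20, each = n / 20))
  )
  d$y <- 5 * d$strong + rnorm(n)
  sel <- suppressMessages(aic_stepwise(
    d, "y", candidates = list(strong = "strong", noise = "noise"),
    random = "g", family = "gaussian"))
  expect_equal(sel$selected, "strong")

  # all-null candidates select the null model
  d$y2 <- rnorm(n)
  sel0 <- suppressMessages(aic_stepwise(
    d, "y2", candidates = list(a = "strong", b = "noise"),
    random = "g", family = "gaussian"))
  expect_length(sel0$selected, 0)

  # a duplicated predictor: parsimony retains exactly one copy
  d$strong2 <- d$strong
  sel2 <- suppressMessages(aic_stepwise(
    d, "y", candidates = list(s1 = "strong", s2 = "strong2"),
    random = "g", family = "gaussian"))
  expect_length(sel2$selected, 1)

  # deterministic replay: identical data and order give identical traces
  sel_b <- suppressMessages(aic_stepwise(
    d, "y", candidates = list(strong = "strong", noise = "noise"),
    random = "g", family = "gaussian"))
  expect_equal(sel_b$selected, sel$selected)
  expect_equal(sel_b$trace$aic, sel$trace$aic)
})

test_that("a pure-noise covariate never increases the ML log-likelihood", {
  set.seed(5)
  n <- 300
  d <- tibble::tibble(x = rnorm(n), junk = rnorm(n),
                      g = factor(rep(1:10, each = n / 10)))
  d$y <- d$x + rnorm(n)
  base <- fit_mixed_model(d, "y", "x", "g", "gaussian")
  plus <- fit_mixed_model(d, "y", c("x", "junk"), "g", "gaussian")
  expect_gte(plus$logLik_ml, base$logLik_ml - 1e-6)
  expect_gte(plus$aic, base$aic + 2 - 2 * (plus$logLik_ml - base$logLik_ml) -
               1e-6)
})
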