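test_that("PSRF separates mixed chains from divergent ones", {
  set.seed(14)
  iid <- replicate(4, rnorm(2000), simplify = FALSE)
  expect_lt(psrf(iid), 1.05)
  expect_gt(psrf(iid), 0.995)

  shifted <- list(rnorm(2000), rnorm(2000) + 5)
  expect_gt(psrf(shifted), 1.5)

  # identical duplicated chains: B = 0, PSRF = sqrt((n-1)/n)
  ch <- rnorm(1000)
  expect_equal(psrf(list(ch, ch)), sqrt(999 / 1000))

  expect_warning(r1 <- psrf(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_true(is.na(r1))
})

test_that("psrf_table flags non-converged parameters", {
  set.seed(15)
  mk <- function(shift) cbind(good = rnorm(500), bad = rnorm(500) + shift)
  tb <- psrf_table(list(mk(0), mk(6)))
  expect_true(tb$converged[tb$parameter == "good"])
  expect_false(tb$converged[tb$parameter == "bad"])
})

test_that("Heidelberger-Welch diagnostics pass iid noise and fail drift", {
  set.seed(16)
  draws <- cbind(iid = rnorm(4000),
                 drift = seq(0, 6, length.out = 4000) + rnorm(4000, 0, 0.3),
                 flat = rep(1, 4000))
  out <- mcmc_convergence(draws)
  expect_true(out$stationarity_pass[out$parameter == "iid"])
  expect_gt(out$ess[out$parameter == "iid"], 2500)
  expect_false(out$stationarity_pass[out$parameter == "drift"])
  expect_true(out$degenerate[out$parameter == "flat"])
})

test_that("kernel-density mode finds the density peak", {
  expect_equal(kde_mode(rep(7, 10)), 7)
  set.seed(17)
  x <- c(rnorm(5000, 0, 1), rnorm(500, 4, 0.3))
  expect_lt(abs(kde_mode(x)), 0.3)
})
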