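test_that("relative fitness normalises to mean one", {
  expect_equal(relative_fitness(c(2, 2)), c(1, 1))
  expect_equal(relative_fitness(c(0, 2)), c(0, 2))
  set.seed(18)
  W <- rpois(100, 2)
  expect_equal(mean(relative_fitness(W)), 1)
  expect_error(relative_fitness(c(0, 0)), "positive")
})

test_that("the selection differential is cov(trait, relative fitness)", {
  # hand-computed oracle: trait [0,1,2], W [0,1,2] -> w = [0,1,2], S = 1
  s <- selection_differential(c(0, 1, 2), c(0, 1, 2), n_boot = 0)
  expect_equal(s$S, 1.0)
  expect_equal(s$S_std, 1.0)

  s0 <- selection_differential(c(3, 7, 9, 4), rep(2, 4), n_boot = 0)
  expect_equal(s0$S, 0)

  expect_warning(
    sc <- selection_differential(rep(5, 6), c(1, 2, 1, 0, 3, 1),
                                 n_boot = 0),
    "zero trait variance")
  expect_equal(sc$S, 0)
})

test_that("Robertson identity and scale invariance hold on random data", {
  for (r in 1:5) {
    set.seed(30 + r)
    n <- 150
    trait <- rnorm(n, 60, 12)
    W <- rpois(n, pmax(0.1, 2 - 0.02 * (trait - 50)))
    S <- selection_differential(trait, W, n_boot = 0)$S
    # weighted-mean oracle (n-1 covariance correction applied)
    w <- W / mean(W)
    S_oracle <- (sum(trait * w) / n - mean(trait) * mean(w)) * n / (n - 1)
    expect_equal(S, S_oracle, tolerance = 1e-10)
    # invariance to positive rescaling of fitness
    expect_equal(selection_differential(trait, 7.3 * W, n_boot = 0)$S, S)
  }
})

test_that("Lande-Arnold gradients recover linear and quadratic selection", {
  z <- scale(seq(-2, 2, length.out = 200))[, 1]  # mean 0, sd 1 exactly
  trait <- 60 + 10 * z
  w_lin <- 1 + 0.4 * z                           # mean(w) = 1
  g <- suppressWarnings(selection_gradients(trait, w_lin * 2))     # scale-free in W
  expect_equal(g$beta, 0.4, tolerance = 1e-9)
  expect_equal(g$gamma, 0, tolerance = 1e-9)

  # noiseless quadratic with mean relative fitness 1:
  # raw coefficient convention recovers -0.3 exactly, doubled gives -0.6
  w_quad <- 1 - 0.3 * (z^2 - mean(z^2))
  gq <- suppressWarnings(
    selection_gradients(trait, w_quad, quadratic_convention = "raw"))
  expect_equal(gq$gamma, -0.3, tolerance = 1e-9)
  gq2 <- suppressWarnings(selection_gradients(trait, w_quad))
  expect_equal(gq2$gamma, -0.6, tolerance = 1e-9)
  expect_error(selection_gradients(rep(1, 10), rpois(10, 2)), "constant")
})

test_that("beta equals the standardized differential under linear fitness", {
  set.seed(20)
  trait <- rnorm(300, 60, 9)
  z <- scale(trait)[, 1]
  W <- 1 + 0.5 * z  # mean exactly 1, linear in the standardized trait
  beta <- suppressWarnings(selection_gradients(trait, W))$beta
  S_std <- selection_differential(trait, W, n_boot = 0)$S_std
  expect_equal(beta, 0.5, tolerance = 1e-9)
  expect_equal(S_std, 0.5, tolerance = 1e-9)
})

test_that("bootstrap standard errors match analytic ones and are seeded", {
  set.seed(21)
  d <- tibble::tibble(x = rnorm(200, 10, 3))
  b1 <- bootstrap_se(function(dd) mean(dd$x), d, B = 2000, seed = 5)
  analytic <- sd(d$x) / sqrt(nrow(d))
  expect_lt(abs(b1$se - analytic) / analytic, 0.15)
  b2 <- bootstrap_se(function(dd) mean(dd$x), d, B = 2000, seed = 5)
  expect_identical(b1$se, b2$se)
  bc <- bootstrap_se(function(dd) mean(dd$x),
                     tibble::tibble(x = rep(4, 50)), B = 300, seed = 1)
  expect_equal(bc$se, 0)
})
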